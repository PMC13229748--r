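# File readers/writers and configuration loading.

#' Read a video as a frame source
#'
#' Accepts a directory of numbered PNG frames (`frame_000001.png`, ...).
#' Frames are returned on the 0-255 intensity scale in RGB order. The frame
#' rate must be supplied (PNG directories carry no timing metadata); omitting
#' it is an explicit error, never a silent default.
#'
#' @param path Directory containing PNG frames.
#' @param fps Frame rate in Hz.
#' @return A frame-source function `f(i)` with attributes `n_frames` and
#'   `fps`, suitable for [extract_channels()].
#' @export
read_video <- function(path, fps) {
  if (missing(fps) || is.null(fps)) {
    stop("invalid-parameter: fps must be given for a frame directory")
  }
  if (!dir.exists(path)) stop("I/O error: no such directory: ", path)
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("I/O error: no frame_*.png files in ", path)
  f <- function(i) {
    if (i < 1 || i > length(files)) {
      stop("I/O error: frame index ", i, " out of range")
    }
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 2) {
      img <- array(rep(img, 3), c(dim(img), 3))
    }
    img[, , 1:3, drop = FALSE] * 255
  }
  attr(f, "n_frames") <- length(files)
  attr(f, "fps") <- fps
  f
}

#' Read a respiration-belt CSV
#'
#' Expects a header and two numeric columns (time in seconds, respiration
#' amplitude). The sampling rate is inferred from the median timestamp
#' spacing; if spacing deviates from uniform by more than 1% the signal is
#' resampled onto a uniform grid with a warning.
#'
#' @param path CSV file path.
#' @return A [temporal_signal()] labeled `belt` whose `t0` is the first
#'   timestamp.
#' @export
read_belt_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("I/O error: belt CSV needs two columns")
  t <- df[[1]]; v <- df[[2]]
  bad <- which(!is.finite(t) | !is.finite(v))
  if (length(bad) > 0) {
    stop("I/O error: malformed belt row at line ", bad[1] + 1)
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("I/O error: non-increasing timestamps in belt CSV")
  med <- stats::median(dt)
  fs <- 1 / med
  if (max(abs(dt - med)) > 0.01 * med) {
    warning("read_belt_csv: non-uniform timestamps; resampling to ",
            signif(fs, 6), " Hz")
    grid <- seq(t[1], t[length(t)], by = med)
    v <- stats::approx(t, v, xout = grid)$y
    t <- grid
  }
  temporal_signal(v, fs, "belt", t0 = t[1])
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return Full configuration list.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(default_config())
  user <- yaml::read_yaml(path)
  merge_config(user)
}

#' Write a signal set as a CSV dump
#'
#' @param channels Named list of [temporal_signal()]s at a common rate.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signals_csv <- function(channels, path) {
  n <- length(channels[[1]]$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / channels[[1]]$fs)
  for (nm in names(channels)) df[[nm]] <- channels[[nm]]$samples
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
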