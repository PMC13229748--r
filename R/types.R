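#' Bounding box in frame coordinates
#'
#' Integer pixel rectangle with top-left origin, y pointing downward and a
#' half-open extent `[x, x + w) x [y, y + h)` (0-based corner).
#'
#' @param x,y Top-left corner in pixels (0-based).
#' @param w,h Width and height in pixels; both must be positive.
#' @return An object of class `bounding_box`.
#' @examples
#' bounding_box(100, 50, 80, 100)
#' @export
bounding_box <- function(x, y, w, h) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(w), is.numeric(h))
  if (w <= 0 || h <= 0) {
    stop("invalid-parameter: bounding box width and height must be positive")
  }
  structure(list(x = x, y = y, w = w, h = h), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box x=%g y=%g w=%g h=%g>\n", x$x, x$y, x$w, x$h))
  invisible(x)
}

#' Clip a bounding box to frame bounds
#'
#' @param box A [bounding_box()].
#' @param frame_w,frame_h Frame width and height in pixels.
#' @return The clipped `bounding_box`, or `NULL` with class attribute
#'   `"chest_out_of_frame"`-style signalling left to callers when empty.
#' @keywords internal
clip_box <- function(box, frame_w, frame_h) {
  x0 <- max(box$x, 0)
  y0 <- max(box$y, 0)
  x1 <- min(box$x + box$w, frame_w)
  y1 <- min(box$y + box$h, frame_h)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  bounding_box(x0, y0, x1 - x0, y1 - y0)
}

#' Intersection-over-union of two bounding boxes
#'
#' @param a,b [bounding_box()] objects.
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

#' Uniformly sampled temporal signal
#'
#' A 1-D physiological signal with its sampling rate, channel label and start
#' time. The channel label is free-form but the pipeline uses
#' `face_rppg`, `face_motion`, `chest_rppg`, `chest_motion`, `fused`, `belt`
#' and `predicted`.
#'
#' @param samples Numeric vector of samples; must be finite.
#' @param fs Sampling rate in Hz; must be positive.
#' @param channel Channel label.
#' @param t0 Start time in seconds.
#' @return An object of class `temporal_signal`.
#' @export
temporal_signal <- function(samples, fs, channel = "signal", t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  if (!is.numeric(fs) || fs <= 0) {
    stop("invalid-parameter: sampling rate fs must be positive")
  }
  if (any(!is.finite(samples))) {
    stop("invalid-parameter: temporal_signal samples must be finite")
  }
  structure(
    list(samples = as.numeric(samples), fs = fs,
         channel = channel, t0 = t0),
    class = "temporal_signal"
  )
}

#' @export
print.temporal_signal <- function(x, ...) {
  cat(sprintf("<temporal_signal '%s': %d samples @ %g Hz, t0=%g s, %.1f s>\n",
              x$channel, length(x$samples), x$fs, x$t0,
              length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.temporal_signal <- function(x) length(x$samples)

#' Time axis of a temporal signal
#' @param signal A [temporal_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(signal) {
  signal$t0 + (seq_along(signal$samples) - 1) / signal$fs
}

# Replace the sample vector, keeping metadata.
with_samples <- function(signal, samples, channel = signal$channel) {
  temporal_signal(samples, signal$fs, channel, signal$t0)
}
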