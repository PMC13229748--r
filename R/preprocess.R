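# Temporal denoising and per-frame photometric normalization.

#' Temporal Gaussian smoothing
#'
#' Convolution with a unit-sum sampled Gaussian kernel of half-width `k`
#' (`2k + 1` taps); boundaries handled by reflection. Normalizing the kernel
#' to unit sum preserves constants, so the smoother attenuates flicker and
#' sensor noise while leaving the 0.1-0.6 Hz respiratory band essentially
#' untouched at typical frame rates.
#'
#' @param series Numeric vector (an intensity sequence).
#' @param sigma Gaussian SD in frames.
#' @param half_width_k Kernel half-width in frames; must be at least
#'   `ceiling(3 * sigma)` so the truncated kernel captures the Gaussian mass.
#' @return Smoothed numeric vector of the same length.
#' @export
temporal_gaussian_smooth <- function(series, sigma = 2, half_width_k = 6) {
  if (sigma <= 0) stop("invalid-parameter: sigma must be positive")
  if (half_width_k < ceiling(3 * sigma)) {
    stop("invalid-parameter: half_width_k must be >= ceiling(3*sigma)")
  }
  n <- length(series)
  if (n <= 2 * half_width_k) {
    stop("invalid-parameter: series shorter than the smoothing kernel")
  }
  tau <- -half_width_k:half_width_k
  kern <- exp(-tau^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  # reflect boundaries
  ext <- c(series[(half_width_k + 1):2], series,
           series[(n - 1):(n - half_width_k)])
  out <- stats::filter(ext, kern, method = "convolution", sides = 2)
  as.numeric(out[(half_width_k + 1):(half_width_k + n)])
}

#' Gaussian smoothing kernel (unit sum)
#' @inheritParams temporal_gaussian_smooth
#' @return Numeric vector of `2 * half_width_k + 1` kernel taps.
#' @export
gaussian_kernel <- function(sigma = 2, half_width_k = 6) {
  tau <- -half_width_k:half_width_k
  kern <- exp(-tau^2 / (2 * sigma^2))
  kern / sum(kern)
}

#' Per-frame photometric normalization within the skin mask
#'
#' Standardizes masked pixel values to zero mean and unit SD (population SD
#' over all masked values, all channels jointly), reducing inter-subject
#' reflectance and illumination differences. Masked-out pixels stay zero.
#'
#' @param frame ROI image (H x W x 3 array or H x W matrix), already masked.
#' @param mask A `skin_mask` of matching spatial shape.
#' @return Normalized frame; signals a `degenerate_frame` condition (class
#'   `degenerate_frame`) when the mask has fewer than 2 pixels or zero
#'   variance.
#' @export
normalize_frame <- function(frame, mask) {
  idx <- mask$values == 1
  if (sum(idx) < 2) {
    stop(structure(class = c("degenerate_frame", "error", "condition"),
                   list(message = "degenerate-frame: mask has < 2 pixels",
                        call = sys.call())))
  }
  vals <- if (is.matrix(frame)) frame[idx] else {
    c(frame[, , 1][idx], frame[, , 2][idx], frame[, , 3][idx])
  }
  mu <- mean(vals)
  sd_p <- sqrt(mean((vals - mu)^2))
  if (sd_p <= 0) {
    stop(structure(class = c("degenerate_frame", "error", "condition"),
                   list(message = "degenerate-frame: zero variance in mask",
                        call = sys.call())))
  }
  if (is.matrix(frame)) {
    out <- matrix(0, nrow(frame), ncol(frame))
    out[idx] <- (frame[idx] - mu) / sd_p
    return(out)
  }
  out <- array(0, dim(frame))
  for (ch in 1:3) {
    plane <- frame[, , ch]
    o <- out[, , ch]
    o[idx] <- (plane[idx] - mu) / sd_p
    out[, , ch] <- o
  }
  out
}
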