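# Color-space conversions for skin segmentation.
#
# Frames are H x W x 3 numeric arrays, RGB channel order, 8-bit intensity
# scale (0-255, fractional values allowed internally).

#' Convert an RGB frame to YCrCb
#'
#' Full-range 8-bit YCrCb (JPEG convention): `Y = 0.299 R + 0.587 G + 0.114 B`,
#' `Cr = 0.713 (R - Y) + 128`, `Cb = 0.564 (B - Y) + 128`.
#'
#' @param frame H x W x 3 RGB array on the 0-255 scale.
#' @return H x W x 3 array with channels Y, Cr, Cb.
#' @export
rgb_to_ycrcb <- function(frame) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cr <- 0.713 * (r - y) + 128
  cb <- 0.564 * (b - y) + 128
  out <- array(0, dim(frame))
  out[, , 1] <- y; out[, , 2] <- cr; out[, , 3] <- cb
  out
}

#' Convert an RGB frame to HSV on an 8-bit scale
#'
#' Standard RGB to HSV transform with all three channels rescaled to 0-255
#' (hue's full circle maps to 255). Uses [grDevices::rgb2hsv()].
#'
#' @param frame H x W x 3 RGB array on the 0-255 scale.
#' @return H x W x 3 array with channels H, S, V, each in 0-255.
#' @export
rgb_to_hsv8 <- function(frame) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  d <- dim(frame)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(frame[, , 1]),
    g = as.vector(frame[, , 2]),
    b = as.vector(frame[, , 3]),
    maxColorValue = 255
  )
  out <- array(0, d)
  out[, , 1] <- matrix(hsv[1, ] * 255, d[1], d[2])
  out[, , 2] <- matrix(hsv[2, ] * 255, d[1], d[2])
  out[, , 3] <- matrix(hsv[3, ] * 255, d[1], d[2])
  out
}

#' Convert an RGB frame to grayscale luminance
#'
#' @param frame H x W x 3 RGB array.
#' @return H x W matrix of luminance values.
#' @export
rgb_to_gray <- function(frame) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}
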