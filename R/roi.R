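# Face/chest ROI extraction and skin segmentation.

#' Haar-like rectangle feature
#'
#' Sum of intensities over the white rectangles minus the sum over the black
#' rectangles — the primitive underlying cascade face detectors.
#'
#' @param image Intensity matrix (rows = y, columns = x).
#' @param spec List with `white_rects` and `black_rects`, each a list of
#'   [bounding_box()]es lying inside the image.
#' @return Scalar feature value.
#' @export
haar_feature <- function(image, spec) {
  stopifnot(is.matrix(image),
            length(spec$white_rects) >= 1, length(spec$black_rects) >= 1)
  sum_rect <- function(b) {
    if (b$x < 0 || b$y < 0 ||
        b$x + b$w > ncol(image) || b$y + b$h > nrow(image)) {
      stop("invalid-parameter: Haar rectangle outside the image")
    }
    sum(image[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)])
  }
  sum(vapply(spec$white_rects, sum_rect, numeric(1))) -
    sum(vapply(spec$black_rects, sum_rect, numeric(1)))
}

#' Oracle face detector for synthetic scenes
#'
#' Returns the scene's ground-truth face box regardless of the frame content;
#' used to isolate downstream stages from detection error in tests.
#'
#' @param scene A [synthetic_scene()].
#' @return A detector function `f(frame) -> bounding_box`.
#' @export
oracle_face_detector <- function(scene) {
  force(scene)
  function(frame) scene$face_box
}

#' Skin-blob face detector
#'
#' Detector for frames without an external cascade model: segments skin
#' pixels (combined YCrCb/HSV thresholds), labels connected components, and
#' among components of at least `min_area` pixels returns the bounding box of
#' the one with the topmost centroid (a seated subject's face lies above the
#' chest). Signals `face-not-found` (via `stop`) when no component qualifies.
#'
#' @param thr [skin_thresholds()].
#' @param min_area Minimum component area in pixels.
#' @return A detector function `f(frame) -> bounding_box`.
#' @export
skin_blob_face_detector <- function(thr = skin_thresholds(), min_area = 100) {
  function(frame) {
    mask <- combine_masks(skin_mask_ycrcb(frame, thr),
                          skin_mask_hsv(frame, thr))
    lab <- EBImage::bwlabel(mask$values)
    if (max(lab) == 0) stop("face-not-found: no skin-colored region")
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= min_area)
    if (length(keep) == 0) stop("face-not-found: no skin component above min_area")
    cent_y <- vapply(keep, function(k) mean(which(lab == k, arr.ind = TRUE)[, 1]),
                     numeric(1))
    k <- keep[which.min(cent_y)]
    px <- which(lab == k, arr.ind = TRUE)
    bounding_box(min(px[, 2]) - 1, min(px[, 1]) - 1,
                 max(px[, 2]) - min(px[, 2]) + 1,
                 max(px[, 1]) - min(px[, 1]) + 1)
  }
}

#' Detect the face bounding box in one frame
#'
#' The detector is pluggable: supply [oracle_face_detector()] for synthetic
#' scenes or [skin_blob_face_detector()] for plain frames. When a detector
#' returns several candidate boxes, the largest-area box wins (single seated
#' subject assumed). When detection fails and `previous` is given, the
#' previous frame's box is reused (tracking by persistence); with no previous
#' box the `face-not-found` condition propagates.
#'
#' @param frame H x W x 3 RGB array.
#' @param detector Function mapping a frame to a `bounding_box` or a list of
#'   candidate boxes.
#' @param previous Optional box from the previous frame.
#' @return A [bounding_box()].
#' @export
detect_face <- function(frame, detector, previous = NULL) {
  stopifnot(length(dim(frame)) == 3, all(dim(frame)[1:2] > 0))
  res <- tryCatch(detector(frame), error = function(e) e)
  if (inherits(res, "error")) {
    if (!is.null(previous)) return(previous)
    stop(res)
  }
  if (inherits(res, "bounding_box")) return(res)
  # list of candidates: largest area wins
  areas <- vapply(res, function(b) b$w * b$h, numeric(1))
  res[[which.max(areas)]]
}

#' Project the chest ROI below a detected face
#'
#' The chest box spans `y in [y + h, y + alpha * h)` vertically and
#' `x in [x - beta * w, x + (1 + beta) * w)` horizontally, then is clipped to
#' the frame. Defaults `alpha = 2.5`, `beta = 0.2`.
#'
#' @param face A [bounding_box()] for the face.
#' @param alpha Vertical extent factor (chest bottom at `y + alpha * h`).
#' @param beta Horizontal expansion as a fraction of the face width per side.
#' @param frame_w,frame_h Frame size for clipping.
#' @return A clipped [bounding_box()]; signals `chest-out-of-frame` when the
#'   clipped region is empty.
#' @export
project_chest_roi <- function(face, alpha = 2.5, beta = 0.2,
                              frame_w, frame_h) {
  stopifnot(inherits(face, "bounding_box"), alpha > 1, beta >= 0)
  raw <- list(x = face$x - beta * face$w,
              y = face$y + face$h,
              w = (1 + 2 * beta) * face$w,
              h = (alpha - 1) * face$h)
  box <- clip_box(bounding_box(raw$x, raw$y, raw$w, raw$h), frame_w, frame_h)
  if (is.null(box)) stop("chest-out-of-frame: projected chest box empty after clipping")
  box
}

#' Skin-color thresholds
#'
#' Chrominance (Cr/Cb), hue and saturation bounds on the 8-bit scale. The
#' defaults are widely used skin-detection ranges; all bounds are inclusive.
#'
#' @param cr_min,cr_max,cb_min,cb_max YCrCb chrominance bounds.
#' @param h_min,h_max,s_min,s_max HSV hue/saturation bounds (0-255 scale,
#'   hue's full circle = 255).
#' @return An object of class `skin_thresholds`.
#' @export
skin_thresholds <- function(cr_min = 133, cr_max = 173,
                            cb_min = 77, cb_max = 127,
                            h_min = 0, h_max = 50,
                            s_min = 58, s_max = 174) {
  stopifnot(cr_min <= cr_max, cb_min <= cb_max,
            h_min <= h_max, s_min <= s_max)
  structure(list(cr_min = cr_min, cr_max = cr_max, cb_min = cb_min,
                 cb_max = cb_max, h_min = h_min, h_max = h_max,
                 s_min = s_min, s_max = s_max),
            class = "skin_thresholds")
}

new_skin_mask <- function(values, frame_index = NA_integer_) {
  structure(list(values = values, frame_index = frame_index),
            class = "skin_mask")
}

#' Binary skin mask from YCrCb chrominance thresholds
#'
#' @param frame H x W x 3 RGB array (0-255 scale).
#' @param thr [skin_thresholds()].
#' @param frame_index Optional frame index carried on the mask.
#' @return A `skin_mask` whose `values` matrix is 1 where both Cr and Cb lie
#'   within bounds.
#' @export
skin_mask_ycrcb <- function(frame, thr = skin_thresholds(), frame_index = NA) {
  # direct Cr/Cb computation (equivalent to rgb_to_ycrcb, Y not kept)
  d <- dim(frame)
  r <- matrix(frame[, , 1], d[1], d[2])
  g <- matrix(frame[, , 2], d[1], d[2])
  b <- matrix(frame[, , 3], d[1], d[2])
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cr <- 0.713 * (r - y) + 128
  cb <- 0.564 * (b - y) + 128
  m <- (cr >= thr$cr_min & cr <= thr$cr_max &
          cb >= thr$cb_min & cb <= thr$cb_max) * 1
  new_skin_mask(m, frame_index)
}

#' Binary skin mask from HSV hue/saturation thresholds
#'
#' @inheritParams skin_mask_ycrcb
#' @return A `skin_mask` with 1 where both H and S lie within bounds.
#' @export
skin_mask_hsv <- function(frame, thr = skin_thresholds(), frame_index = NA) {
  # direct H/S computation (equivalent to rgb_to_hsv8, V not needed)
  d <- dim(frame)
  r <- matrix(frame[, , 1], d[1], d[2])
  g <- matrix(frame[, , 2], d[1], d[2])
  b <- matrix(frame[, , 3], d[1], d[2])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  s <- d / (mx + (mx <= 0)) * 255  # S = 0 where the pixel is black
  hdeg <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  ir <- nz & mx == r
  ig <- nz & mx == g & !ir
  ib <- nz & !ir & !ig
  hdeg[ir] <- 60 * (((g[ir] - b[ir]) / d[ir]) %% 6)
  hdeg[ig] <- 60 * ((b[ig] - r[ig]) / d[ig] + 2)
  hdeg[ib] <- 60 * ((r[ib] - g[ib]) / d[ib] + 4)
  h <- hdeg / 360 * 255
  m <- (h >= thr$h_min & h <= thr$h_max &
          s >= thr$s_min & s <= thr$s_max) * 1
  new_skin_mask(m, frame_index)
}

#' Combine two skin masks by logical OR
#'
#' A pixel is skin when either color-space test accepts it.
#'
#' @param a,b `skin_mask` objects of identical shape.
#' @return Combined `skin_mask`.
#' @export
combine_masks <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop("invalid-parameter: mask shapes differ")
  }
  new_skin_mask((a$values | b$values) * 1, a$frame_index)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Offsets of a disc structuring element of the given radius.
disc_offsets <- local({
  cache <- list()
  function(radius) {
    key <- as.character(radius)
    if (is.null(cache[[key]])) {
      g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
      cache[[key]] <<- g[g$dr^2 + g$dc^2 <= radius^2, ]
    }
    cache[[key]]
  }
})

# Binary erosion/dilation with a disc structuring element via shifted
# min/max accumulation (exact, and fast on the small ROI crops). Radius 1
# (the plus-shaped element) has a specialized padding-free path.
morph_binary <- function(m, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  if (radius < 1) return(m)
  if (radius == 1) {
    H <- nrow(m); W <- ncol(m)
    fill <- if (op == "erode") 1 else 0
    up <- rbind(m[-1, , drop = FALSE], rep(fill, W))
    dn <- rbind(rep(fill, W), m[-H, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], rep(fill, H))
    rt <- cbind(rep(fill, H), m[, -W, drop = FALSE])
    return(if (op == "erode") pmin(m, up, dn, lf, rt)
           else pmax(m, up, dn, lf, rt))
  }
  offs <- disc_offsets(radius)
  fill <- if (op == "erode") 1 else 0
  acc <- m
  for (i in seq_len(nrow(offs))) {
    if (offs$dr[i] == 0 && offs$dc[i] == 0) next
    s <- shift_mat(m, offs$dr[i], offs$dc[i], fill)
    acc <- if (op == "erode") pmin(acc, s) else pmax(acc, s)
  }
  acc
}

# Separable Gaussian blur via shifted row/column accumulation (replicated
# borders), specialized for small mask matrices.
blur_mat <- function(m, sigma) {
  k <- max(1, ceiling(3 * sigma))
  w <- exp(-(-k:k)^2 / (2 * sigma^2))
  w <- w / sum(w)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (j in -k:k) {
    src <- pmin(pmax(seq_len(H) + j, 1), H)
    out <- out + w[j + k + 1] * m[src, , drop = FALSE]
  }
  out2 <- matrix(0, H, W)
  for (j in -k:k) {
    src <- pmin(pmax(seq_len(W) + j, 1), W)
    out2 <- out2 + w[j + k + 1] * out[, src, drop = FALSE]
  }
  out2
}

#' Refine a binary skin mask
#'
#' Gaussian blur, re-threshold at 0.5, then morphological opening followed by
#' closing with disc structuring elements — suppresses speckle noise and small
#' isolated regions while filling pinholes.
#'
#' @param mask A `skin_mask`.
#' @param blur_sigma Gaussian blur SD in pixels (0 disables blurring).
#' @param open_radius,close_radius Disc radii in pixels (0 disables the step).
#' @return Refined binary `skin_mask`.
#' @export
refine_mask <- function(mask, blur_sigma = 1, open_radius = 1,
                        close_radius = 1) {
  m <- mask$values
  if (blur_sigma > 0) {
    m <- (blur_mat(m, blur_sigma) >= 0.5) * 1
  }
  if (open_radius > 0) {
    m <- morph_binary(morph_binary(m, open_radius, "erode"),
                      open_radius, "dilate")
  }
  if (close_radius > 0) {
    m <- morph_binary(morph_binary(m, close_radius, "dilate"),
                      close_radius, "erode")
  }
  new_skin_mask(m, mask$frame_index)
}

#' Apply a binary mask to a frame
#'
#' Elementwise product: non-skin pixels are zeroed in every channel so only
#' skin-reflective regions contribute downstream.
#'
#' @param frame H x W x 3 RGB array (or H x W matrix).
#' @param mask A `skin_mask` of matching spatial shape.
#' @return Masked array of the same shape as `frame`.
#' @export
apply_mask <- function(frame, mask) {
  m <- mask$values
  if (is.matrix(frame)) {
    if (!identical(dim(frame), dim(m))) stop("invalid-parameter: shape mismatch")
    return(frame * m)
  }
  if (!identical(dim(frame)[1:2], dim(m))) {
    stop("invalid-parameter: shape mismatch")
  }
  out <- frame
  for (ch in seq_len(dim(frame)[3])) out[, , ch] <- frame[, , ch] * m
  out
}

#' Crop a frame (or matrix) to a bounding box
#'
#' @param frame H x W x 3 array or H x W matrix.
#' @param box A [bounding_box()] (0-based, half-open).
#' @return The cropped region.
#' @export
crop_frame <- function(frame, box) {
  ri <- (box$y + 1):(box$y + box$h)
  ci <- (box$x + 1):(box$x + box$w)
  if (is.matrix(frame)) frame[ri, ci, drop = FALSE] else frame[ri, ci, , drop = FALSE]
}
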