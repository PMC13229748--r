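# Lucas-Kanade optical flow for chest-motion extraction.
#
# Pyramidal, window-based LK with Shi-Tomasi corner selection and an
# intensity-centroid fallback. Implemented directly (no R binding exposes an
# LK tracker); all steps vectorized over feature points.

# Central-difference gradients of an image matrix.
image_gradients <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# 2x2-mean downsample for the pyramid.
downsample2 <- function(img) {
  H <- 2 * (nrow(img) %/% 2); W <- 2 * (ncol(img) %/% 2)
  img <- img[1:H, 1:W, drop = FALSE]
  (img[seq(1, H, 2), seq(1, W, 2)] + img[seq(2, H, 2), seq(1, W, 2)] +
     img[seq(1, H, 2), seq(2, W, 2)] + img[seq(2, H, 2), seq(2, W, 2)]) / 4
}

# Bilinear sampling of img at (row, col) coordinate vectors (1-based, may be
# fractional). Out-of-range coordinates are clamped.
bilinear_sample <- function(img, r, cc) {
  H <- nrow(img); W <- ncol(img)
  r <- pmin(pmax(r, 1), H - 1e-6)
  cc <- pmin(pmax(cc, 1), W - 1e-6)
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  i00 <- (c0 - 1) * H + r0
  i10 <- (c0 - 1) * H + r1
  i01 <- (c1 - 1) * H + r0
  i11 <- (c1 - 1) * H + r1
  (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
}

#' Shi-Tomasi corner detection
#'
#' Minimum eigenvalue of the locally summed structure tensor, thresholded at
#' `quality * max`, greedily selected in score order with a minimum
#' separation.
#'
#' @param img Grayscale matrix.
#' @param max_corners Maximum number of corners returned.
#' @param quality Relative quality threshold.
#' @param min_dist Minimum separation between corners in pixels.
#' @param block Half-width of the structure-tensor summation window.
#' @return Matrix with columns `row`, `col` (1-based, integer positions);
#'   zero rows when no corner qualifies.
#' @export
detect_corners <- function(img, max_corners = 200, quality = 0.01,
                           min_dist = 5, block = 2) {
  g <- image_gradients(img)
  box <- matrix(1, 2 * block + 1, 2 * block + 1)
  sxx <- EBImage::filter2(g$gx * g$gx, box, boundary = 0)
  syy <- EBImage::filter2(g$gy * g$gy, box, boundary = 0)
  sxy <- EBImage::filter2(g$gx * g$gy, box, boundary = 0)
  tr <- sxx + syy
  det_d <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  lmin <- (tr - det_d) / 2
  # exclude a border margin where windows would leave the image
  margin <- block + 2
  score <- lmin
  score[c(seq_len(margin), nrow(img) - seq_len(margin) + 1), ] <- 0
  score[, c(seq_len(margin), ncol(img) - seq_len(margin) + 1)] <- 0
  thr <- quality * max(score)
  cand <- which(score >= thr & score > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("row", "col"))))
  ord <- order(score[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  sel <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(sel) == 0 ||
        min((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2) >= min_dist^2) {
      sel <- rbind(sel, p)
      if (nrow(sel) >= max_corners) break
    }
  }
  colnames(sel) <- c("row", "col")
  sel
}

# Single-level iterative LK for a set of points. pts: n x 2 (row, col),
# init_flow: n x 2 (drow, dcol). Returns list(flow, valid).
# Template windows are sampled at integer positions (points are rounded for
# the template only); the moving image is sampled bilinearly.
lk_level <- function(prev, nxt, pts, init_flow, win = 15, iters = 3) {
  n <- nrow(pts)
  hw <- (win - 1) / 2
  H <- nrow(prev); W <- ncol(prev)
  if (H < win + 2 || W < win + 2) {
    # level too small to refine; pass the current estimate through unchanged
    return(list(flow = init_flow, valid = rep(TRUE, n)))
  }
  g <- image_gradients(prev)
  ptr <- pmin(pmax(round(pts[, 1]), 1 + hw), H - hw)
  ptc <- pmin(pmax(round(pts[, 2]), 1 + hw), W - hw)
  # linear indices of each point's integer window: n x win^2
  off_lin <- as.vector(outer(-hw:hw, (-hw:hw) * H, "+"))
  lin <- outer((ptc - 1) * H + ptr, off_lin, "+")
  ix <- g$gx[lin]; dim(ix) <- dim(lin)
  iy <- g$gy[lin]; dim(iy) <- dim(lin)
  ip <- prev[lin]; dim(ip) <- dim(lin)
  gxx <- rowSums(ix * ix); gyy <- rowSums(iy * iy); gxy <- rowSums(ix * iy)
  det_g <- gxx * gyy - gxy^2
  valid <- det_g > 1e-6
  flow <- init_flow
  for (it in seq_len(iters)) {
    # warped window of the moving image: one fractional offset per point, so
    # bilinear interpolation reduces to four integer-shifted gathers
    r0 <- floor(flow[, 1]); c0 <- floor(flow[, 2])
    r0 <- pmin(pmax(r0, 1 + hw - ptr), H - 1 - hw - ptr)
    c0 <- pmin(pmax(c0, 1 + hw - ptc), W - 1 - hw - ptc)
    frr <- pmin(pmax(flow[, 1] - r0, 0), 1)
    fcc <- pmin(pmax(flow[, 2] - c0, 0), 1)
    shift <- c0 * H + r0
    l00 <- lin + shift
    jp <- (1 - frr) * (1 - fcc) * nxt[l00] +
      frr * (1 - fcc) * nxt[l00 + 1] +
      (1 - frr) * fcc * nxt[l00 + H] +
      frr * fcc * nxt[l00 + H + 1]
    dim(jp) <- dim(lin)
    e <- ip - jp
    bx <- rowSums(e * ix); by <- rowSums(e * iy)
    # solve [gxx gxy; gxy gyy] d = [bx; by]
    dcol <- (gyy * bx - gxy * by) / det_g
    drow <- (gxx * by - gxy * bx) / det_g
    dcol[!valid] <- 0; drow[!valid] <- 0
    flow[, 1] <- flow[, 1] + drow
    flow[, 2] <- flow[, 2] + dcol
  }
  H <- nrow(prev); W <- ncol(prev)
  inb <- pts[, 1] + flow[, 1] > 1 & pts[, 1] + flow[, 1] < H &
    pts[, 2] + flow[, 2] > 1 & pts[, 2] + flow[, 2] < W
  list(flow = flow, valid = valid & inb)
}

#' Pyramidal Lucas-Kanade flow between two frames for given points
#'
#' @param prev,nxt Grayscale matrices of identical size.
#' @param pts n x 2 matrix of point positions (row, col; 1-based).
#' @param win Integration window size in pixels (odd).
#' @param levels Pyramid levels.
#' @param iters Refinement iterations per level.
#' @param presmooth_sigma Gaussian pre-smoothing SD in pixels (0 disables; default 2).
#'   Textures with near-Nyquist content bias finite-difference gradients
#'   low, which makes the least-squares flow overshoot; mild smoothing
#'   before differentiation removes that bias.
#' @return List with `flow` (n x 2 matrix of row/col displacements) and
#'   `valid` (logical vector).
#' @export
lk_flow <- function(prev, nxt, pts, win = 15, levels = 3, iters = 3,
                    presmooth_sigma = 2) {
  stopifnot(identical(dim(prev), dim(nxt)), nrow(pts) >= 1)
  if (presmooth_sigma > 0) {
    prev <- blur_mat(prev, presmooth_sigma)
    nxt <- blur_mat(nxt, presmooth_sigma)
  }
  pyr_p <- list(prev); pyr_n <- list(nxt)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyr_p[[l]])) < 2 * (win + 2)) break
    pyr_p[[l + 1]] <- downsample2(pyr_p[[l]])
    pyr_n[[l + 1]] <- downsample2(pyr_n[[l]])
  }
  L <- length(pyr_p)
  flow <- matrix(0, nrow(pts), 2)
  valid <- rep(TRUE, nrow(pts))
  for (l in L:1) {
    scale <- 2^(l - 1)
    res <- lk_level(pyr_p[[l]], pyr_n[[l]],
                    (pts - 1) / scale + 1, flow / scale,
                    win = win, iters = iters)
    flow <- res$flow * scale
    valid <- valid & res$valid
  }
  list(flow = flow, valid = valid)
}

# Row-centroid fallback: vertical centroid of edge energy per frame.
centroid_row_signal <- function(frames) {
  vapply(frames, function(f) {
    g <- abs(image_gradients(f)$gy)
    w <- rowSums(g)
    if (sum(w) <= 0) return(NA_real_)
    sum(seq_along(w) * w) / sum(w)
  }, numeric(1))
}

#' Extract a vertical motion signal from an ROI sequence
#'
#' Tracks corner features frame-to-frame with pyramidal Lucas-Kanade flow and
#' forms, per frame, a weighted mean of the vertical flow components with
#' weights increasing linearly from 0.2 at the top row of the ROI to 1.0 at
#' the bottom (emphasizing thoracic motion). The cumulative sum yields a
#' displacement signal. Features are re-detected when fewer than
#' `redetect_below` survive; if no features are trackable at all the
#' row-centroid fallback is used, and if that also fails a
#' `no-motion-signal` error is raised.
#'
#' @param roi_frames List of grayscale matrices (same size).
#' @param fs Frame rate in Hz.
#' @param max_corners,win,levels,iters Lucas-Kanade settings.
#' @param redetect_below Re-detect features when fewer remain valid.
#' @param presmooth_sigma Gaussian pre-smoothing of the frames in pixels
#'   (see [lk_flow()]); applied once per frame here.
#' @return A [temporal_signal()] labeled `motion` (displacement in pixels;
#'   positive = downward).
#' @export
extract_motion <- function(roi_frames, fs, max_corners = 200, win = 15,
                           levels = 3, iters = 3, redetect_below = 50,
                           presmooth_sigma = 2) {
  n <- length(roi_frames)
  stopifnot(n >= 2)
  if (presmooth_sigma > 0) {
    # blur each frame once here rather than twice inside per-pair tracking
    roi_frames <- lapply(roi_frames, blur_mat, sigma = presmooth_sigma)
  }
  H <- nrow(roi_frames[[1]])
  row_weight <- function(rows) 0.2 + 0.8 * (rows - 1) / max(H - 1, 1)

  pts <- detect_corners(roi_frames[[1]], max_corners = max_corners)
  use_fallback <- nrow(pts) == 0
  vel <- numeric(n)  # per-frame vertical velocity (rows/frame)
  if (!use_fallback) {
    for (i in seq_len(n - 1)) {
      if (nrow(pts) < redetect_below) {
        fresh <- detect_corners(roi_frames[[i]], max_corners = max_corners)
        if (nrow(fresh) > nrow(pts)) pts <- fresh
      }
      if (nrow(pts) == 0) { use_fallback <- TRUE; break }
      res <- lk_flow(roi_frames[[i]], roi_frames[[i + 1]], pts,
                     win = win, levels = levels, iters = iters,
                     presmooth_sigma = 0)
      ok <- res$valid
      if (!any(ok)) { use_fallback <- TRUE; break }
      w <- row_weight(pts[ok, 1])
      vel[i + 1] <- sum(w * res$flow[ok, 1]) / sum(w)
      pts <- pts[ok, , drop = FALSE] + res$flow[ok, , drop = FALSE]
    }
  }
  if (use_fallback) {
    cent <- centroid_row_signal(roi_frames)
    if (all(is.na(cent))) stop("no-motion-signal: no trackable structure in ROI")
    disp <- cent - cent[which(!is.na(cent))[1]]
    return(fill_gaps_signal(disp, fs, "motion"))
  }
  temporal_signal(cumsum(vel), fs, "motion")
}
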