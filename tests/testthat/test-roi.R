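# ROI extraction: Haar features, face detection contracts, chest projection
# geometry, skin masks in both color spaces, mask refinement and application.

test_that("haar_feature equals white-minus-black intensity sums", {
  img <- matrix(c(5, 2, 1, 2), 2, 2)  # columns: (5,2), (1,2)
  spec <- list(white_rects = list(bounding_box(0, 0, 1, 2)),
               black_rects = list(bounding_box(1, 0, 1, 2)))
  expect_equal(haar_feature(img, spec), (5 + 2) - (1 + 2))

  # constant image with equal-area regions gives zero
  cimg <- matrix(3, 4, 4)
  spec2 <- list(white_rects = list(bounding_box(0, 0, 2, 4)),
                black_rects = list(bounding_box(2, 0, 2, 4)))
  expect_equal(haar_feature(cimg, spec2), 0)

  # random image / random rects against a brute-force double loop
  set.seed(11)
  rimg <- matrix(runif(64), 8, 8)
  brute <- function(img, b) {
    s <- 0
    for (r in (b$y + 1):(b$y + b$h)) for (cc in (b$x + 1):(b$x + b$w)) {
      s <- s + img[r, cc]
    }
    s
  }
  for (k in 1:5) {
    w <- bounding_box(sample(0:4, 1), sample(0:4, 1), sample(1:3, 1), sample(1:3, 1))
    b <- bounding_box(sample(0:4, 1), sample(0:4, 1), sample(1:3, 1), sample(1:3, 1))
    spec3 <- list(white_rects = list(w), black_rects = list(b))
    expect_equal(haar_feature(rimg, spec3), brute(rimg, w) - brute(rimg, b))
  }
  expect_error(
    haar_feature(img, list(white_rects = list(bounding_box(0, 0, 5, 5)),
                           black_rects = list(bounding_box(0, 0, 1, 1)))),
    "invalid-parameter")
})

test_that("detect_face honors the oracle, largest-area tie-break and persistence", {
  sc <- quick_scene(duration_s = 10)
  frame <- render_frames(sc, 1)[[1]]
  box <- detect_face(frame, oracle_face_detector(sc))
  expect_equal(box, sc$face_box)
  expect_equal(box_iou(box, sc$face_box), 1.0)

  two_boxes <- function(frame) list(bounding_box(0, 0, 10, 10),
                                    bounding_box(5, 5, 20, 20))
  expect_equal(detect_face(frame, two_boxes)$w, 20)

  failing <- function(frame) stop("face-not-found")
  prev <- bounding_box(1, 2, 3, 4)
  expect_equal(detect_face(frame, failing, previous = prev), prev)
  expect_error(detect_face(frame, failing), "face-not-found")

  # blank frame through the skin-blob detector: nothing skin-colored
  blank <- array(0, c(40, 40, 3))
  expect_error(skin_blob_face_detector()(blank), "face-not-found")
})

test_that("skin-blob detector finds the synthetic face region", {
  sc <- quick_scene(duration_s = 10)
  frame <- render_frames(sc, 1)[[1]]
  box <- skin_blob_face_detector()(frame)
  expect_gt(box_iou(box, sc$face_box), 0.8)
})

test_that("chest projection follows the printed geometry and clipping rules", {
  face <- bounding_box(100, 50, 80, 100)
  chest <- project_chest_roi(face, alpha = 2.5, beta = 0.2, 640, 480)
  expect_equal(chest$x, 84)
  expect_equal(chest$x + chest$w, 196)
  expect_equal(chest$y, 150)
  expect_equal(chest$y + chest$h, 300)

  # beta = 0 preserves the face x-range
  c0 <- project_chest_roi(face, alpha = 2.5, beta = 0, 640, 480)
  expect_equal(c(c0$x, c0$w), c(face$x, face$w))

  # clipping at the frame bottom
  low <- bounding_box(0, 400, 50, 60)
  cl <- project_chest_roi(low, 2.5, 0.2, 640, 480)
  expect_equal(cl$y, 460)
  expect_equal(cl$y + cl$h, 480)

  # fully out of frame
  edge <- bounding_box(0, 420, 50, 60)
  expect_error(project_chest_roi(edge, 1.5, 0.2, 640, 480),
               "chest-out-of-frame")
})

test_that("chest projection is translation-equivariant before clipping", {
  face <- bounding_box(50, 40, 30, 40)
  big <- 10000
  base <- project_chest_roi(face, 2.5, 0.2, big, big)
  shifted <- project_chest_roi(bounding_box(face$x + 7, face$y + 11, face$w, face$h),
                               2.5, 0.2, big, big)
  expect_equal(shifted$x - base$x, 7)
  expect_equal(shifted$y - base$y, 11)
  expect_equal(c(shifted$w, shifted$h), c(base$w, base$h))
})

test_that("YCrCb mask matches the standard transform on known pixels", {
  px <- function(rgb) array(rep(rgb, each = 1), c(1, 1, 3))
  skin <- px(c(230, 195, 175))
  expect_equal(skin_mask_ycrcb(skin)$values[1, 1], 1)
  blue <- px(c(0, 0, 255))
  expect_equal(skin_mask_ycrcb(blue)$values[1, 1], 0)
  # collapsed thresholds that no pixel attains give an all-zero mask
  thr <- skin_thresholds(cr_min = 255, cr_max = 255)
  expect_true(all(skin_mask_ycrcb(skin, thr)$values == 0))
  # agreement with the full conversion helper
  set.seed(3)
  rnd <- array(runif(30 * 3, 0, 255), c(5, 6, 3))
  ycc <- rgb_to_ycrcb(rnd)
  thr0 <- skin_thresholds()
  manual <- (ycc[, , 2] >= thr0$cr_min & ycc[, , 2] <= thr0$cr_max &
               ycc[, , 3] >= thr0$cb_min & ycc[, , 3] <= thr0$cb_max) * 1
  expect_equal(skin_mask_ycrcb(rnd)$values, manual)
})

test_that("HSV mask matches the standard transform and edge cases", {
  px <- function(rgb) array(rep(rgb, each = 1), c(1, 1, 3))
  skin <- px(c(230, 195, 175))   # H ~ 15.5, S ~ 61 on the 0-255 scale
  expect_equal(skin_mask_hsv(skin)$values[1, 1], 1)
  gray <- px(c(120, 120, 120))   # S = 0, below s_min
  expect_equal(skin_mask_hsv(gray)$values[1, 1], 0)
  full <- skin_thresholds(h_min = 0, h_max = 255, s_min = 0, s_max = 255)
  set.seed(4)
  rnd <- array(runif(60, 0, 255), c(4, 5, 3))
  expect_true(all(skin_mask_hsv(rnd, full)$values == 1))
  # fast path agrees with grDevices-based conversion
  hsv <- rgb_to_hsv8(rnd)
  thr0 <- skin_thresholds()
  manual <- (hsv[, , 1] >= thr0$h_min & hsv[, , 1] <= thr0$h_max &
               hsv[, , 2] >= thr0$s_min & hsv[, , 2] <= thr0$s_max) * 1
  expect_equal(skin_mask_hsv(rnd)$values, manual)
})

test_that("mask combination is an elementwise OR with the expected algebra", {
  m <- function(v) structure(list(values = v, frame_index = 1),
                             class = "skin_mask")
  a <- m(matrix(c(1, 0), 1)); b <- m(matrix(c(0, 0), 1))
  expect_equal(combine_masks(a, b)$values, matrix(c(1, 0), 1))
  set.seed(5)
  x <- m(matrix(rbinom(30, 1, 0.5), 5, 6))
  y <- m(matrix(rbinom(30, 1, 0.5), 5, 6))
  expect_equal(combine_masks(x, x)$values, x$values)            # idempotent
  expect_equal(combine_masks(x, y)$values, combine_masks(y, x)$values)
  expect_equal(combine_masks(x, y)$values, (x$values | y$values) * 1)
  expect_error(combine_masks(x, m(matrix(0, 2, 2))), "invalid-parameter")
})

test_that("mask refinement removes specks, fills holes, and stays binary", {
  m <- function(v) structure(list(values = v, frame_index = 1),
                             class = "skin_mask")
  speck <- matrix(0, 15, 15); speck[8, 8] <- 1
  out <- refine_mask(m(speck), blur_sigma = 0, open_radius = 1,
                     close_radius = 0)
  expect_true(all(out$values == 0))

  block <- matrix(0, 24, 24); block[3:22, 3:22] <- 1; block[12, 12] <- 0
  filled <- refine_mask(m(block), blur_sigma = 0, open_radius = 0,
                        close_radius = 1)
  expect_equal(filled$values[12, 12], 1)

  ones <- matrix(1, 20, 20)
  kept <- refine_mask(m(ones), blur_sigma = 1, open_radius = 1,
                      close_radius = 1)
  expect_true(all(kept$values[3:18, 3:18] == 1))
  expect_true(all(kept$values %in% c(0, 1)))
})

test_that("apply_mask zeroes non-skin pixels exactly", {
  set.seed(6)
  frame <- array(runif(36 * 3, 0, 255), c(6, 6, 3))
  m <- function(v) structure(list(values = v, frame_index = 1),
                             class = "skin_mask")
  ones <- m(matrix(1, 6, 6)); zeros <- m(matrix(0, 6, 6))
  expect_equal(apply_mask(frame, ones), frame)
  expect_true(all(apply_mask(frame, zeros) == 0))
  rnd <- m(matrix(rbinom(36, 1, 0.5), 6, 6))
  out <- apply_mask(frame, rnd)
  for (ch in 1:3) expect_equal(out[, , ch], frame[, , ch] * rnd$values)
  expect_error(apply_mask(frame, m(matrix(1, 3, 3))), "shape mismatch")
})
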