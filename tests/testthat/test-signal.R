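# Signal derivation and conditioning: rPPG means, motion extraction,
# detrending, bandpass, three-sigma normalization, SNR, fusion, windowing.

test_that("rPPG extraction averages masked green values and fills gaps", {
  mk <- function(g, maskv) {
    frame <- array(0, c(2, 2, 3)); frame[, , 2] <- g
    mask <- structure(list(values = maskv, frame_index = 1),
                      class = "skin_mask")
    list(frame = frame, mask = mask)
  }
  ones <- matrix(1, 2, 2); none <- matrix(0, 2, 2)
  a <- mk(matrix(1, 2, 2), ones)
  b <- mk(matrix(9, 2, 2), none)   # degenerate frame
  c_ <- mk(matrix(3, 2, 2), ones)
  s <- extract_rppg(list(a$frame, b$frame, c_$frame),
                    list(a$mask, b$mask, c_$mask), fs = 30)
  expect_equal(s$samples, c(1, 2, 3))  # middle value linearly interpolated
  expect_error(extract_rppg(list(a$frame), list(mk(ones, none)$mask), 30),
               "no-signal")
})

test_that("detrending removes lines exactly and leaves residual mean/slope zero", {
  s <- temporal_signal(c(1, 2, 3), 10)
  expect_equal(detrend_signal(s)$samples, c(0, 0, 0))
  set.seed(10)
  x <- temporal_signal(rnorm(500), 30)
  d <- detrend_signal(x)
  expect_equal(mean(d$samples), 0, tolerance = 1e-12)
  t <- seq_along(d$samples)
  expect_lt(abs(stats::coef(stats::lm(d$samples ~ t))[2]), 1e-12)
  expect_gt(stats::cor(d$samples, x$samples), 0.99)  # white noise barely changed
})

test_that("zero-phase Butterworth matches its analytic squared-magnitude response", {
  fs <- 30
  t <- (0:(60 * fs - 1)) / fs
  spec <- filter_spec(0.1, 0.6, 4)
  mid <- 300:1500

  inband <- temporal_signal(sin(2 * pi * 0.3 * t), fs)
  y <- bandpass_signal(inband, spec)
  amp <- sqrt(2 * mean(y$samples[mid]^2))
  expect_equal(amp, butterworth_bandpass_gain(0.3, spec), tolerance = 0.02)
  expect_gt(amp, 0.98)
  # zero phase: peak correlation at zero lag
  cc <- stats::ccf(y$samples[mid], inband$samples[mid], lag.max = 5,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  dc <- temporal_signal(rep(5, length(t)), fs)
  expect_lt(abs(mean(bandpass_signal(dc, spec)$samples)), 1e-3)

  hi <- temporal_signal(sin(2 * pi * 2 * t), fs)
  yh <- bandpass_signal(hi, spec)
  att_db <- -20 * log10(sqrt(2 * mean(yh$samples[mid]^2)))
  expect_gt(att_db, 40)
  expect_error(bandpass_signal(temporal_signal(t, 1), spec),
               "invalid-parameter")
})

test_that("three-sigma normalization follows the population convention", {
  s <- temporal_signal(c(1, 2, 3), 10)
  out <- three_sigma_normalize(s)
  expect_equal(out$samples, (c(1, 2, 3) - 2) / (3 * sqrt(2 / 3)))
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  set.seed(12)
  x <- temporal_signal(rnorm(5000), 30)
  n <- three_sigma_normalize(x)
  expect_equal(sd_pop(n$samples), 1 / 3, tolerance = 1e-12)
  expect_gt(mean(abs(n$samples) <= 1), 0.99)  # three-sigma rule
  expect_error(three_sigma_normalize(temporal_signal(rep(2, 10), 30)),
               "degenerate-signal")
})

test_that("spectral SNR behaves for pure tones and white noise", {
  fs <- 30; t <- (0:(60 * fs - 1)) / fs
  tone <- temporal_signal(sin(2 * pi * 0.25 * t), fs)
  expect_gt(compute_snr(tone, 0.25), 20)
  set.seed(13)
  snrs <- replicate(20, {
    compute_snr(temporal_signal(rnorm(length(t)), fs), 0.25)
  })
  expect_equal(mean(snrs), 10 * log10(0.1 / 0.85), tolerance = 1)
})

test_that("fusion obeys the printed weights and algebraic identities", {
  fs <- 30
  chest <- temporal_signal(rep(1, 100), fs)
  face <- temporal_signal(rep(0, 100), fs)
  expect_equal(fuse_signals(chest, face)$samples, rep(0.8, 100))
  expect_equal(fuse_signals(chest, face, fusion_weights(0.5, 0.5))$samples,
               rep(0.5, 100))
  expect_equal(fuse_signals(chest, face, fusion_weights(1, 0))$samples,
               chest$samples)
  set.seed(14)
  x <- temporal_signal(rnorm(100), fs)
  expect_equal(fuse_signals(x, x, fusion_weights(0.7, 0.3))$samples,
               x$samples, tolerance = 1e-12)
  expect_error(fusion_weights(0.8, 0.3), "invalid-parameter")
  expect_error(fuse_signals(chest, temporal_signal(1:10, fs)),
               "invalid-parameter")
})

test_that("windowing yields the documented counts and boundaries", {
  fs <- 30
  sigs <- lapply(c("face_rppg", "face_motion", "chest_rppg", "chest_motion"),
                 function(ch) temporal_signal(seq_len(1800), fs, ch))
  w <- make_windows(sigs, 256, 32)
  expect_length(w, 49)  # floor((1800 - 256) / 32) + 1
  expect_equal(w[[1]]$start_index, 0)
  expect_equal(dim(w[[1]]$values), c(256, 4))
  expect_equal(w[[2]]$values[1, 1], 33)

  sigs300 <- lapply(sigs, function(s) temporal_signal(s$samples[1:300], fs, s$channel))
  expect_length(make_windows(sigs300, 300, 300), 1)
  w2 <- make_windows(sigs300, 100, 100)
  expect_length(w2, 3)
  expect_equal(vapply(w2, function(x) x$start_index, numeric(1)), c(0, 100, 200))
  expect_error(make_windows(sigs300, 400, 32), "too-short")
})

test_that("fusion-weight sweep runs and facial weight rescues disturbed motion", {
  # the Table-style weight sweep is runnable end to end
  scenes <- make_cohort(6, tone = rep(c("light", "dark"), 3), seed = 3,
                        duration_s = 40)
  sw <- sweep_fusion_weights(scenes)
  expect_equal(sw$w_chest, seq(0.5, 1.0, by = 0.1))
  expect_equal(sw$w_chest + sw$w_face, rep(1, 6))
  expect_true(all(is.finite(sw$mae_bpm)))

  # complementary-information direction: on recordings with strong body
  # motion and good rPPG, chest-only estimation is clearly worse than a
  # fused weighting
  li <- make_cohort(12, tone = "light", seed = 31, noise_sd = 4)
  swl <- sweep_fusion_weights(li)
  expect_gt(swl$mae_bpm[swl$w_chest == 1.0], swl$mae_bpm[swl$w_chest == 0.6])
})

test_that("conditioning pipeline is invariant to constant and linear offsets", {
  set.seed(15)
  fs <- 30; t <- (0:(45 * fs - 1)) / fs
  x <- temporal_signal(sin(2 * pi * 0.2 * t) + 0.2 * rnorm(length(t)), fs)
  base <- condition_signal(x)
  shifted <- condition_signal(with_samples(x, x$samples + 7 + 0.5 * t))
  expect_equal(shifted$samples[200:1100], base$samples[200:1100],
               tolerance = 0.02)
})

test_that("overlap averaging reconstructs overlapping window predictions", {
  p1 <- rep(1, 4); p2 <- rep(3, 4)
  out <- overlap_average(list(p1, p2), starts = c(0, 2), total_len = 6, fs = 1)
  expect_equal(out$samples, c(1, 1, 2, 2, 3, 3))
})

test_that("Lucas-Kanade recovers synthetic vertical motion and rejects horizontal", {
  # band-limited texture translated analytically (a valid imaging model for
  # sub-pixel motion); axis-separable waves so component selection is tested
  # free of the aperture problem
  H <- 60; W <- 80
  ry <- matrix(rep(1:H, W), H, W)
  cx <- matrix(rep(1:W, each = H), H, W)
  img_at <- function(dy, dx = 0) {
    v <- 0
    set.seed(99)
    for (k in 1:20) {
      fy <- runif(1, 0.03, 0.2); fx <- runif(1, 0.03, 0.2)
      p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
      v <- v + sin(2 * pi * fy * (ry - dy) + p1) +
        sin(2 * pi * fx * (cx - dx) + p2)
    }
    v * 2
  }
  n <- 90; fs <- 30
  d <- 2 * sin(2 * pi * 0.5 * (0:(n - 1)) / fs)
  frames_v <- lapply(d, function(dd) img_at(dd))
  mv <- extract_motion(frames_v, fs)
  expect_gt(abs(stats::cor(mv$samples, d)), 0.95)
  # window-based LK with iterative bilinear warping carries a small
  # systematic gain (~15% here); the spectral rate estimate is invariant to
  # amplitude scale, so the displacement scale only needs to be roughly right
  amp_ratio <- (max(mv$samples) - min(mv$samples)) / (max(d) - min(d))
  expect_equal(amp_ratio, 1, tolerance = 0.2)

  # static frames: no motion signal
  ms <- extract_motion(rep(frames_v[1], 30), fs)
  expect_lt(max(abs(ms$samples)), 1e-6)

  # equal-magnitude horizontal translation leaks less than 5%
  frames_h <- lapply(d, function(dd) img_at(0, dd))
  mh <- extract_motion(frames_h, fs)
  expect_lt(max(abs(mh$samples)), 0.05 * max(abs(mv$samples)))
})

test_that("chest motion from rendered video tracks the true displacement", {
  sc <- quick_scene(rr_bpm = 12, duration_s = 15, chest_disp_px = 3)
  src <- scene_frame_source(sc)
  crops <- lapply(seq_len(attr(src, "n_frames")), function(i) {
    rgb_to_gray(crop_frame(src(i), sc$chest_box))
  })
  m <- extract_motion(crops, sc$fps, levels = 1, iters = 2)
  d_true <- -sc$chest_disp_px * scene_waveform(sc)$samples  # rows grow downward
  expect_gt(stats::cor(m$samples, d_true), 0.95)
})
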