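# Synthetic generator: waveform spectral fidelity, rendering ground truth,
# bundle construction, belt CSV round trips, determinism.

test_that("respiratory waveform has the requested fundamental and length", {
  w <- generate_respiratory_waveform(15, 60, 30, harmonic_frac = 0)
  expect_equal(length(w$samples), 1800)
  expect_equal(w$fs, 30)
  # pure sinusoid at 0.25 Hz: periodogram argmax within one FFT bin
  n <- length(w$samples)
  p <- Mod(stats::fft(w$samples))^2
  freqs <- (seq_len(n) - 1) * 30 / n
  half <- freqs <= 15
  f_hat <- freqs[half][which.max(p[half])]
  expect_lt(abs(f_hat - 0.25), 30 / n + 1e-12)

  # 6 BPM sits at the lower edge of the respiratory band
  w6 <- generate_respiratory_waveform(6, 60, 30)
  p6 <- Mod(stats::fft(w6$samples))^2
  f6 <- freqs[half][which.max(p6[half])]
  expect_lt(abs(f6 - 0.1), 30 / n + 1e-12)
})

test_that("waveform spectral fidelity holds across rates (FFT oracle)", {
  for (rr in c(6, 10, 15, 20, 30)) {
    w <- generate_respiratory_waveform(rr, 60, 30, harmonic_frac = 0.3)
    n <- length(w$samples)
    p <- Mod(stats::fft(w$samples))^2
    freqs <- (seq_len(n) - 1) * 30 / n
    sel <- freqs >= 0.05 & freqs <= 0.65
    f_hat <- freqs[sel][which.max(p[sel])]
    expect_lt(abs(f_hat - rr / 60), 30 / n + 1e-12)
  }
})

test_that("waveform rejects invalid parameters", {
  expect_error(generate_respiratory_waveform(-1, 60, 30), "invalid-parameter")
  expect_error(generate_respiratory_waveform(15, 60, 0), "invalid-parameter")
  expect_error(generate_respiratory_waveform(15, 2, 30), "invalid-parameter")
})

test_that("noiseless rendering makes face green an affine function of the waveform", {
  sc <- quick_scene(rr_bpm = 12, duration_s = 12)
  src <- scene_frame_source(sc)
  r <- scene_waveform(sc)$samples
  t <- (seq_along(r) - 1) / sc$fps
  pulse <- sin(2 * pi * (sc$hr_bpm / 60) * t + 0.7)
  idx <- seq(1, 300, by = 10)
  g <- vapply(idx, function(i) {
    masked_green_mean(src(i), structure(
      list(values = face_ellipse_mask(sc), frame_index = i),
      class = "skin_mask"))
  }, numeric(1))
  expected <- sc$tone$resp_amp * r[idx] + sc$tone$pulse_amp * pulse[idx]
  fit <- stats::lm(g ~ expected)
  # an essentially perfect fit is the point here; summary()'s caveat about
  # it is expected
  sm <- suppressWarnings(summary(fit))
  expect_gt(sm$r.squared, 0.999999)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 1e-6)
})

test_that("chest mask centroid tracks the breathing displacement", {
  sc <- quick_scene(rr_bpm = 12, duration_s = 12, chest_disp_px = 3)
  src <- scene_frame_source(sc)
  r <- scene_waveform(sc)$samples
  idx <- seq(1, 300, by = 5)
  cent <- vapply(idx, function(i) {
    frame <- src(i)
    m <- combine_masks(skin_mask_ycrcb(frame), skin_mask_hsv(frame))
    rows <- which(rowSums(m$values[, (sc$torso_x0 + 1):sc$torso_x1]) > 0)
    rows <- rows[rows > sc$torso_ytop - 10]
    min(rows)
  }, numeric(1))
  # top edge rises (smaller row) on inhalation: strong negative correlation
  expect_lt(stats::cor(cent, r[idx]), -0.95)
})

test_that("rendering is deterministic: same seed gives identical frames", {
  sc <- synthetic_scene(duration_s = 10, seed = 77)
  f1 <- render_frames(sc, indices = c(1, 50, 150))
  f2 <- render_frames(sc, indices = c(1, 50, 150))
  expect_identical(f1, f2)
  # and streaming access matches batch rendering
  src <- scene_frame_source(sc)
  expect_identical(src(50), f1[[2]])
})

test_that("channel bundle respects construction and determinism", {
  sc <- synthetic_scene(rr_bpm = 12, duration_s = 30, seed = 4)
  b1 <- generate_channel_bundle(sc)
  b2 <- generate_channel_bundle(sc)
  expect_identical(b1, b2)
  expect_named(b1, c("face_rppg", "face_motion", "chest_rppg",
                     "chest_motion", "reference"))
  expect_equal(length(b1$face_rppg$samples), 900)

  # face resp_amp = 0 kills the respiratory band power of face rPPG
  sc0 <- synthetic_scene(rr_bpm = 12, duration_s = 30, seed = 4, noise_sd = 0,
                         tone = tone_profile("x", base_rgb = c(230, 195, 175),
                                             pulse_amp = 0, resp_amp = 0))
  b0 <- generate_channel_bundle(sc0)
  expect_lt(stats::var(b0$face_rppg$samples), 1e-20)
  expect_gt(stats::var(b0$chest_motion$samples), 1)
})

test_that("dark preset yields lower face-rPPG respiratory band power than light", {
  for (seed in 1:3) {
    sl <- synthetic_scene(rr_bpm = 14, seed = seed, tone = "light")
    sd_ <- synthetic_scene(rr_bpm = 14, seed = seed, tone = "dark")
    p_band <- function(sc) {
      s <- condition_signal(generate_channel_bundle(sc)$face_rppg)
      compute_snr(generate_channel_bundle(sc)$face_rppg, 14 / 60)
    }
    expect_gt(p_band(sl), p_band(sd_))
  }
})

test_that("belt CSV writes the stated timestamps and round-trips", {
  s <- temporal_signal(c(0.1, 0.2, 0.3), fs = 10)
  path <- tempfile(fileext = ".csv")
  write_belt_csv(s, offset_s = 0, path = path)
  df <- read.csv(path)
  expect_equal(df$time_s, c(0, 0.1, 0.2))
  write_belt_csv(s, offset_s = 0.5, path = path)
  expect_equal(read.csv(path)$time_s[1], 0.5)

  sc <- synthetic_scene(rr_bpm = 10, duration_s = 30, belt_offset_s = 0.5)
  belt <- scene_belt_signal(sc)
  write_belt_csv(belt, path = path)
  back <- read_belt_csv(path)
  expect_equal(back$samples, belt$samples, tolerance = 1e-9)
  expect_equal(back$fs, sc$belt_fs)
  expect_equal(back$t0, 0.5)
})

test_that("scene validation enforces the evaluated RR range and amplitudes", {
  expect_error(synthetic_scene(rr_bpm = 4), "6-30")
  expect_error(synthetic_scene(rr_bpm = 35), "6-30")
  expect_error(synthetic_scene(noise_sd = -1), "invalid-parameter")
  expect_error(tone_profile("light", base_rgb = c(10, 10, 10),
                            pulse_amp = -1, resp_amp = 1),
               "invalid-parameter")
})
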