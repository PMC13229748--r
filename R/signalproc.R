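# Respiratory signal derivation and conditioning: rPPG means, detrending,
# zero-phase Butterworth bandpass, three-sigma normalization, SNR, fusion,
# windowing.

#' Mean green intensity over masked pixels of one frame
#' @param frame H x W x 3 array.
#' @param mask A `skin_mask`.
#' @return Scalar mean, or `NA` when the mask is empty.
#' @export
masked_green_mean <- function(frame, mask) {
  idx <- mask$values == 1
  if (!any(idx)) return(NA_real_)
  mean(frame[, , 2][idx])
}

#' Extract an rPPG signal from a masked ROI sequence
#'
#' Averages green-channel intensities over skin pixels per frame (the green
#' band carries the strongest blood-volume modulation). Degenerate frames
#' (empty mask) are filled by linear interpolation from neighbors.
#'
#' @param roi_frames List of H x W x 3 ROI arrays (masked, possibly
#'   normalized).
#' @param masks List of `skin_mask` objects, one per frame.
#' @param fs Sampling rate (frames per second).
#' @return A [temporal_signal()] labeled `rppg`.
#' @export
extract_rppg <- function(roi_frames, masks, fs) {
  stopifnot(length(roi_frames) >= 1, length(roi_frames) == length(masks))
  vals <- mapply(masked_green_mean, roi_frames, masks)
  fill_gaps_signal(vals, fs, "rppg")
}

# Linear interpolation of NA samples; errors when all samples are NA.
fill_gaps_signal <- function(vals, fs, channel) {
  if (all(is.na(vals))) stop("no-signal: all frames degenerate")
  if (anyNA(vals)) {
    idx <- which(!is.na(vals))
    vals <- stats::approx(idx, vals[idx], xout = seq_along(vals),
                          rule = 2)$y
  }
  temporal_signal(vals, fs, channel)
}

#' Remove the least-squares linear trend from a signal
#'
#' @param signal A [temporal_signal()] (length >= 3).
#' @return Detrended [temporal_signal()]; residuals have zero mean and zero
#'   slope.
#' @export
detrend_signal <- function(signal) {
  x <- signal$samples
  stopifnot(length(x) >= 3)
  t <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, t), x)
  with_samples(signal, as.numeric(fit$residuals))
}

#' Filter band specification
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.1, high_hz = 0.6, order = 4) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "filter_spec")
}

#' Zero-phase Butterworth bandpass filter
#'
#' Fourth-order (by default) Butterworth bandpass applied forward and
#' backward ([signal::filtfilt()]), so the net phase response is zero and the
#' magnitude response is squared. The input is extended by odd reflection
#' (about three periods of the low band edge) before filtering to suppress
#' edge transients, then trimmed.
#'
#' @param x A [temporal_signal()].
#' @param spec A [filter_spec()]; default 0.1-0.6 Hz, order 4.
#' @return Filtered [temporal_signal()].
#' @export
bandpass_signal <- function(x, spec = filter_spec()) {
  fs <- x$fs
  if (spec$high_hz >= fs / 2) {
    stop("invalid-parameter: band edge at or above Nyquist frequency")
  }
  n <- length(x$samples)
  if (n <= 3 * spec$order) {
    stop("invalid-parameter: signal too short for the filter order")
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  s <- x$samples
  pad <- min(n - 1, round(3 * fs / spec$low_hz))
  left <- 2 * s[1] - s[(pad + 1):2]
  right <- 2 * s[n] - s[(n - 1):(n - pad)]
  ext <- c(left, s, right)
  y <- signal::filtfilt(bf, ext)
  with_samples(x, y[(pad + 1):(pad + n)])
}

#' Analytic squared-magnitude response of the zero-phase Butterworth bandpass
#'
#' Forward-backward filtering squares the magnitude response; this returns
#' `|H(j 2 pi f)|^2` of the analog prototype mapped to the band, i.e. the
#' amplitude gain experienced by a sinusoid at `f`.
#'
#' @param f Frequency in Hz (vectorized).
#' @param spec A [filter_spec()].
#' @return Amplitude gain (unitless).
#' @export
butterworth_bandpass_gain <- function(f, spec = filter_spec()) {
  # analog bandpass prototype: |H|^2 = 1 / (1 + ( (w^2 - w0^2) / (B w) )^(2n) )
  w <- 2 * pi * f
  w1 <- 2 * pi * spec$low_hz; w2 <- 2 * pi * spec$high_hz
  w0 <- sqrt(w1 * w2); B <- w2 - w1
  h2 <- 1 / (1 + ((w^2 - w0^2) / (B * w))^(2 * spec$order))
  h2  # forward-backward pass: amplitude gain = |H|^2
}

#' Three-sigma normalization
#'
#' `(x - mean(x)) / (3 * sd(x))` with the population SD, so roughly 99.7% of
#' a Gaussian signal's samples land in `[-1, 1]` — making amplitudes
#' comparable across subjects and skin tones.
#'
#' @param signal A [temporal_signal()].
#' @return Normalized [temporal_signal()]; signals `degenerate-signal` on a
#'   constant input.
#' @export
three_sigma_normalize <- function(signal) {
  x <- signal$samples
  mu <- mean(x)
  sd_p <- sqrt(mean((x - mu)^2))
  if (sd_p <= 0) stop("degenerate-signal: constant input")
  with_samples(signal, (x - mu) / (3 * sd_p))
}

#' Spectral signal-to-noise ratio around a reference frequency
#'
#' `10 log10` of the periodogram power within `f_ref +/- half_width` over the
#' power in `noise_band` excluding that band.
#'
#' @param signal A [temporal_signal()].
#' @param f_ref Reference (true respiratory) frequency in Hz.
#' @param half_width Signal band half-width in Hz.
#' @param noise_band Total band considered, in Hz.
#' @return SNR in dB (`Inf` with a warning when out-of-band power is zero).
#' @export
compute_snr <- function(signal, f_ref, half_width = 0.05,
                        noise_band = c(0.05, 1.0)) {
  fs <- signal$fs
  stopifnot(f_ref > 0.05, f_ref < fs / 2)
  x <- signal$samples - mean(signal$samples)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  p <- p[half]; freqs <- freqs[half]
  in_sig <- freqs >= f_ref - half_width & freqs <= f_ref + half_width
  in_noise <- freqs >= noise_band[1] & freqs <= noise_band[2] & !in_sig
  ps <- sum(p[in_sig]); pn <- sum(p[in_noise])
  if (pn <= 0) {
    warning("compute_snr: zero out-of-band power; returning Inf")
    return(Inf)
  }
  10 * log10(ps / pn)
}

#' Fusion weights for chest/face signal combination
#' @param w_chest,w_face Non-negative weights summing to 1 (default 0.8/0.2,
#'   favoring the higher-SNR chest signal).
#' @return An object of class `fusion_weights`.
#' @export
fusion_weights <- function(w_chest = 0.8, w_face = 0.2) {
  if (w_chest < 0 || w_face < 0 || abs(w_chest + w_face - 1) > 1e-9) {
    stop("invalid-parameter: fusion weights must be non-negative and sum to 1")
  }
  structure(list(w_chest = w_chest, w_face = w_face), class = "fusion_weights")
}

#' Weighted fusion of chest and face signals
#'
#' `S(t) = w_chest * S_chest(t) + w_face * S_face(t)`. The chest component
#' receives the higher weight because of its stronger respiratory coupling.
#'
#' @param chest,face [temporal_signal()]s of equal length and rate.
#' @param w A [fusion_weights()].
#' @return Fused [temporal_signal()] labeled `fused`.
#' @export
fuse_signals <- function(chest, face, w = fusion_weights()) {
  if (length(chest$samples) != length(face$samples) || chest$fs != face$fs) {
    stop("invalid-parameter: signals must share length and sampling rate")
  }
  temporal_signal(w$w_chest * chest$samples + w$w_face * face$samples,
                  chest$fs, "fused", chest$t0)
}

#' Slice four channel signals into overlapping multi-channel windows
#'
#' Windows start at 0, `stride`, `2 stride`, ... while they fit; channel
#' order is face-rPPG, face-motion, chest-rPPG, chest-motion.
#'
#' @param signals List of four [temporal_signal()]s of equal length and rate,
#'   in channel order.
#' @param win_len Window length in frames (default 256).
#' @param stride Hop between window starts in frames (default 32, i.e. 87.5%
#'   overlap).
#' @return List of `multi_channel_window` objects (fields `values` = T x 4
#'   matrix, `start_index` 0-based, `fs`).
#' @export
make_windows <- function(signals, win_len = 256, stride = 32) {
  stopifnot(length(signals) == 4, stride > 0, stride <= win_len)
  lens <- vapply(signals, function(s) length(s$samples), numeric(1))
  if (length(unique(lens)) != 1) stop("invalid-parameter: unequal signal lengths")
  L <- lens[1]
  if (L < win_len) stop("too-short: signals shorter than one window")
  mat <- vapply(signals, function(s) s$samples, numeric(L))
  starts <- seq(0, L - win_len, by = stride)
  lapply(starts, function(s0) {
    structure(list(values = mat[(s0 + 1):(s0 + win_len), , drop = FALSE],
                   start_index = s0, fs = signals[[1]]$fs),
              class = "multi_channel_window")
  })
}

#' Overlap-average windowed predictions into one waveform
#'
#' Sample positions covered by several windows take the mean of the
#' overlapping predictions.
#'
#' @param preds List of numeric vectors (one prediction per window).
#' @param starts 0-based start indices of the windows.
#' @param total_len Length of the reconstructed sequence.
#' @param fs Sampling rate.
#' @return A [temporal_signal()] labeled `predicted`.
#' @export
overlap_average <- function(preds, starts, total_len, fs) {
  acc <- numeric(total_len)
  cnt <- numeric(total_len)
  for (k in seq_along(preds)) {
    idx <- (starts[k] + 1):(starts[k] + length(preds[[k]]))
    acc[idx] <- acc[idx] + preds[[k]]
    cnt[idx] <- cnt[idx] + 1
  }
  covered <- cnt > 0
  acc[covered] <- acc[covered] / cnt[covered]
  if (!all(covered)) {
    acc <- fill_gaps_signal(ifelse(covered, acc, NA), fs, "predicted")$samples
  }
  temporal_signal(acc, fs, "predicted")
}
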