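# Welch spectral estimation and respiratory-rate conversion.

#' Welch estimator parameters
#'
#' @param seg_len Segment length in samples (default 512, about 17 s at
#'   30 fps).
#' @param overlap_frac Fractional overlap between segments (default 0.5).
#' @param window_fn Taper name; `"hamming"` (default) or `"hann"`.
#' @param nfft Zero-padded FFT length (default 8192: grid step about
#'   0.0037 Hz at 30 fps, i.e. about 0.22 BPM).
#' @param band Respiratory search band in Hz.
#' @return An object of class `welch_params`.
#' @export
welch_params <- function(seg_len = 512, overlap_frac = 0.5,
                         window_fn = "hamming", nfft = 8192,
                         band = c(0.1, 0.6)) {
  stopifnot(overlap_frac >= 0, overlap_frac < 1, nfft >= seg_len,
            band[1] > 0, band[2] > band[1])
  structure(list(seg_len = seg_len, overlap_frac = overlap_frac,
                 window_fn = window_fn, nfft = nfft, band = band),
            class = "welch_params")
}

taper_window <- function(name, n) {
  switch(name,
         hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)),
         stop("invalid-parameter: unknown taper ", name))
}

#' Welch power spectral density
#'
#' Splits the signal into `seg_len`-sample segments overlapped by
#' `overlap_frac`, removes each segment's mean, applies the taper, and
#' averages the modified periodograms on a zero-padded frequency grid.
#' Density scaling: integrating the one-sided PSD over frequency recovers the
#' signal variance (up to taper leakage).
#'
#' @param x A [temporal_signal()].
#' @param params A [welch_params()]. When the signal is shorter than
#'   `seg_len` a single full-length segment is used, with a warning.
#' @return An object of class `spectral_estimate` with `freqs` (Hz), `psd`
#'   (power density), `fs`, and the parameters used.
#' @export
welch_psd <- function(x, params = welch_params()) {
  s <- x$samples
  n <- length(s)
  seg <- params$seg_len
  if (n < seg) {
    warning("welch_psd: signal shorter than seg_len; using a single segment")
    seg <- n
  }
  step <- max(1, round(seg * (1 - params$overlap_frac)))
  starts <- seq(1, n - seg + 1, by = step)
  w <- taper_window(params$window_fn, seg)
  u <- sum(w^2)
  nfft <- max(params$nfft, seg)
  acc <- numeric(nfft)
  for (s0 in starts) {
    segm <- s[s0:(s0 + seg - 1)]
    segm <- (segm - mean(segm)) * w
    acc <- acc + Mod(stats::fft(c(segm, numeric(nfft - seg))))^2
  }
  psd <- acc / (length(starts) * x$fs * u)
  half <- seq_len(floor(nfft / 2) + 1)
  psd <- psd[half]
  # one-sided scaling (double all bins except DC and Nyquist)
  dbl <- rep(2, length(half)); dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[length(half)] <- 1
  psd <- psd * dbl
  freqs <- (half - 1) * x$fs / nfft
  structure(list(freqs = freqs, psd = psd, fs = x$fs, params = params),
            class = "spectral_estimate")
}

#' Dominant frequency within a band
#'
#' Argmax of the PSD restricted to the (inclusive) band; ties break toward
#' the lower frequency.
#'
#' @param est A `spectral_estimate` from [welch_psd()].
#' @param band Two-element band in Hz.
#' @return Peak frequency in Hz.
#' @export
peak_frequency <- function(est, band = c(0.1, 0.6)) {
  sel <- est$freqs >= band[1] & est$freqs <= band[2]
  if (!any(sel)) stop("invalid-parameter: band does not intersect frequency grid")
  f <- est$freqs[sel]; p <- est$psd[sel]
  f[which.max(p)]  # which.max returns the first (lowest-frequency) maximum
}

#' Convert a peak frequency to breaths per minute
#'
#' `RR = f_peak * 60`; equivalently `RR = omega * 60 / (2 pi)` for the
#' angular form — both are computed and asserted equal.
#'
#' @param f_peak Peak frequency in Hz (positive).
#' @return Respiratory rate in BPM.
#' @export
rr_from_frequency <- function(f_peak) {
  if (f_peak <= 0) stop("invalid-parameter: f_peak must be positive")
  rr <- f_peak * 60
  omega <- 2 * pi * f_peak
  stopifnot(isTRUE(all.equal(omega * 60 / (2 * pi), rr)))
  rr
}

#' Post-process a predicted respiratory waveform
#'
#' Detrending followed by the zero-phase Butterworth bandpass (0.1-0.6 Hz by
#' default), removing baseline drift and out-of-band noise before spectral
#' analysis.
#'
#' @param s_hat A [temporal_signal()].
#' @param spec A [filter_spec()].
#' @return Cleaned [temporal_signal()].
#' @export
postprocess_waveform <- function(s_hat, spec = filter_spec()) {
  bandpass_signal(detrend_signal(s_hat), spec)
}

#' Estimate respiratory rate from a waveform
#'
#' Post-processes the waveform, computes the Welch PSD, finds the dominant
#' in-band frequency and converts it to BPM.
#'
#' @param waveform A [temporal_signal()].
#' @param params A [welch_params()].
#' @param postprocess Apply [postprocess_waveform()] first (default TRUE).
#' @return A `spectral_estimate` augmented with `f_peak` (Hz) and `rr_bpm`.
#' @export
estimate_rr <- function(waveform, params = welch_params(),
                        postprocess = TRUE) {
  s <- if (postprocess) postprocess_waveform(
    waveform, filter_spec(params$band[1], params$band[2])) else waveform
  est <- welch_psd(s, params)
  est$f_peak <- peak_frequency(est, params$band)
  est$rr_bpm <- rr_from_frequency(est$f_peak)
  est
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate: %d bins, df=%.4f Hz%s>\n",
              length(x$freqs), diff(x$freqs[1:2]),
              if (!is.null(x$rr_bpm))
                sprintf(", f_peak=%.4f Hz, RR=%.2f BPM", x$f_peak, x$rr_bpm)
              else ""))
  invisible(x)
}
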