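# Camera-belt synchronization, resampling, and agreement metrics.

#' Resample a signal onto a uniform grid at a new rate
#'
#' Linear interpolation over the original time span.
#'
#' @param signal A [temporal_signal()].
#' @param fs_target Target sampling rate in Hz.
#' @return Resampled [temporal_signal()].
#' @export
resample_signal <- function(signal, fs_target) {
  stopifnot(fs_target > 0)
  if (fs_target == signal$fs) return(signal)
  n <- length(signal$samples)
  span <- (n - 1) / signal$fs
  t_old <- (seq_len(n) - 1) / signal$fs
  t_new <- seq(0, span, by = 1 / fs_target)
  y <- stats::approx(t_old, signal$samples, xout = t_new)$y
  temporal_signal(y, fs_target, signal$channel, signal$t0)
}

#' Synchronize a camera-derived signal with the belt reference
#'
#' Both signals must share a sampling rate (resample the belt to the camera
#' rate first) and should be bandpassed to the respiratory band. The lag
#' maximizing the normalized cross-correlation within `+/- max_lag_s` is
#' found (ties break toward the smaller absolute lag); a constant shift is
#' then applied to the camera signal and the overlapping region returned.
#' A positive lag means the camera stream leads the belt (`belt[t]`
#' matches `camera[t + lag]`).
#'
#' @param camera,belt [temporal_signal()]s at the same rate.
#' @param max_lag_s Search half-window in seconds.
#' @param min_peak Peak correlation below which synchronization is declared
#'   unreliable: a `sync-unreliable` warning is issued and lag 0 applied.
#' @return List with `camera`, `belt` (aligned, equal length), `lag_s`,
#'   `lag_samples`, `peak_corr`.
#' @export
synchronize <- function(camera, belt, max_lag_s = 10, min_peak = 0.2) {
  stopifnot(camera$fs == belt$fs)
  fs <- camera$fs
  x <- camera$samples; y <- belt$samples
  L <- min(round(max_lag_s * fs), length(x) - 2, length(y) - 2)
  lags <- -L:L
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      xt <- x[(1 + k):min(length(x), length(y) + k)]
      yt <- y[seq_along(xt)]
    } else {
      yt <- y[(1 - k):min(length(y), length(x) - k)]
      xt <- x[seq_along(yt)]
    }
    den <- sqrt(sum(xt^2) * sum(yt^2))
    if (den <= 0) return(0)
    sum(xt * yt) / den
  }, numeric(1))
  peak <- max(cc)
  if (peak < min_peak) {
    warning("sync-unreliable: correlation peak ", signif(peak, 3),
            " below ", min_peak, "; applying zero lag")
    k <- 0L
  } else {
    at_max <- which(cc >= peak - 1e-12)
    k <- lags[at_max[which.min(abs(lags[at_max]))]]
  }
  if (k >= 0) {
    xa <- x[(1 + k):min(length(x), length(y) + k)]
    ya <- y[seq_along(xa)]
  } else {
    ya <- y[(1 - k):min(length(y), length(x) - k)]
    xa <- x[seq_along(ya)]
  }
  list(camera = with_samples(camera, xa),
       belt = with_samples(belt, ya, "belt"),
       lag_s = k / fs, lag_samples = k, peak_corr = peak)
}

#' Mean absolute error
#' @param ref,pred Numeric vectors of equal nonzero length (reference and
#'   predicted respiratory rates, BPM).
#' @return MAE in the input units.
#' @export
mae <- function(ref, pred) {
  if (length(ref) != length(pred) || length(ref) == 0) {
    stop("invalid-parameter: ref and pred must have equal nonzero length")
  }
  mean(abs(ref - pred))
}

#' Root mean square error
#' @inheritParams mae
#' @return RMSE in the input units.
#' @export
rmse <- function(ref, pred) {
  if (length(ref) != length(pred) || length(ref) == 0) {
    stop("invalid-parameter: ref and pred must have equal nonzero length")
  }
  sqrt(mean((ref - pred)^2))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `pred - ref`; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) SD.
#'
#' @inheritParams mae
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, and
#'   per-point `means`/`diffs` for plotting.
#' @export
bland_altman <- function(ref, pred) {
  if (length(ref) != length(pred) || length(ref) < 2) {
    stop("invalid-parameter: need at least 2 paired observations")
  }
  d <- pred - ref
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       sd_diff = s, means = (ref + pred) / 2, diffs = d)
}

#' Pearson correlation between reference and predicted rates
#' @inheritParams mae
#' @return Product-moment correlation coefficient.
#' @export
pearson_r <- function(ref, pred) {
  if (stats::sd(ref) == 0 || stats::sd(pred) == 0) {
    stop("undefined-correlation: zero variance input")
  }
  stats::cor(ref, pred)
}

#' Build an evaluation report for one group of recordings
#'
#' @param ref,pred Reference and predicted RRs in BPM.
#' @param group Group label (`light`, `dark`, `all`, `cross`, ...).
#' @return An object of class `eval_report` with MAE, RMSE, n, Bland-Altman
#'   statistics and Pearson r (NA when undefined).
#' @export
eval_report <- function(ref, pred, group = "all") {
  ba <- if (length(ref) >= 2) bland_altman(ref, pred) else
    list(mean_diff = pred - ref, loa_low = NA, loa_high = NA, sd_diff = NA)
  r <- tryCatch(pearson_r(ref, pred), error = function(e) NA_real_)
  structure(list(mae = mae(ref, pred), rmse = rmse(ref, pred),
                 n = length(ref),
                 bland_altman = ba[c("mean_diff", "loa_low", "loa_high")],
                 pearson_r = r, group = group,
                 ref = ref, pred = pred),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report '%s': n=%d, MAE=%.3f, RMSE=%.3f BPM, bias=%.3f, LoA=[%.2f, %.2f], r=%.3f>\n",
    x$group, x$n, x$mae, x$rmse, x$bland_altman$mean_diff,
    x$bland_altman$loa_low, x$bland_altman$loa_high, x$pearson_r))
  invisible(x)
}

#' Plot an evaluation report
#'
#' Two-panel base-graphics figure: Bland-Altman agreement (differences vs
#' means with bias and limits of agreement) and the predicted-vs-reference
#' scatter with the identity line.
#'
#' @param x An [eval_report()].
#' @param ... Further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.eval_report <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  ba <- bland_altman(x$ref, x$pred)
  plot(ba$means, ba$diffs, xlab = "Mean RR (BPM)",
       ylab = "Predicted - reference (BPM)",
       main = sprintf("Bland-Altman (%s)", x$group),
       ylim = range(c(ba$diffs, ba$loa_low, ba$loa_high)), ...)
  graphics::abline(h = ba$mean_diff, lty = 1)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  plot(x$ref, x$pred, xlab = "Reference RR (BPM)",
       ylab = "Predicted RR (BPM)",
       main = sprintf("r = %.3f", x$pearson_r), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
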