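# Study-level experiments, shared by the test suite and scripts/acceptance.R.
#
# Problem sizes here are the package's reference experiment designs for
# single-CPU synthetic studies; the methods vignette discusses the choices.

#' Reduced-width network configuration for synthetic studies
#'
#' The full-width default configuration (128 features, 8 heads) matches the
#' architecture description; for parameter-recovery studies on synthetic
#' bundles a narrower network with the identical structure (3 conv blocks,
#' multi-head attention, 2-layer BiLSTM, 3-stage decoder) trains an order of
#' magnitude faster and recovers the respiratory rate equally well, because
#' the mapping from four conditioned channels to the waveform is far simpler
#' than from raw video.
#'
#' @return A [model_config()] with 16 features, 2 heads, 8 hidden LSTM units
#'   per direction and an 8/4/1 decoder.
#' @export
experiment_model_config <- function() {
  model_config(d_model = 16, n_heads = 2, lstm_hidden = 8,
               decoder_channels = c(8, 4, 1))
}

#' Classical-path RR recovery on rendered noiseless videos
#'
#' Renders one 60-s video per (rate, tone) pair at 240 x 180 / 30 fps with
#' sensor noise and drift disabled, runs the full video pipeline (oracle
#' face detection, per-frame dual-color-space skin masks, photometric
#' normalization, rPPG means, Lucas-Kanade chest motion, conditioning,
#' 0.8/0.2 fusion, Welch peak), and tabulates the recovered rates. The flow
#' tracker runs single-level with two iterations and 60 corners:
#' frame-to-frame chest displacement in these scenes is well below one
#' pixel — the regime in which a single linearized Lucas-Kanade solve is
#' exact — and a rigidly translating region needs only a few dozen
#' well-separated features.
#'
#' @param rr_grid True rates in BPM.
#' @param tones Tone presets crossed with `rr_grid`.
#' @param seed Experiment seed.
#' @return Data frame with `rr_true`, `tone`, `rr_est`, `abs_err`.
#' @export
classical_recovery_experiment <- function(rr_grid = c(6, 10, 15, 20, 30),
                                          tones = c("light", "dark"),
                                          seed = 1) {
  grid <- expand.grid(rr = rr_grid, tone = tones,
                      stringsAsFactors = FALSE)
  flow_cfg <- list(flow = list(levels = 1, iters = 2, max_corners = 60,
                               redetect_below = 30))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- synthetic_scene(rr_bpm = grid$rr[i], duration_s = 60, fps = 30,
                          tone = grid$tone[i], noise_sd = 0, drift_amp = 0,
                          seed = derive_seed(seed, 300 + i))
    out <- classical_rr_from_scene(sc, oracle = TRUE, config = flow_cfg)
    data.frame(rr_true = grid$rr[i], tone = grid$tone[i],
               rr_est = out$rr_bpm,
               abs_err = abs(out$rr_bpm - grid$rr[i]))
  })
  do.call(rbind, res)
}

#' Learned-path parameter recovery at the reference scale
#'
#' Trains the reduced-width network on the channel bundles of 40 synthetic
#' subjects (60-s recordings, mixed tones, natural rate variability) for 30
#' epochs at batch size 32, then reports the held-out RR error on 10 unseen
#' subjects.
#'
#' @param seed Experiment seed.
#' @param n_train,n_test Cohort sizes.
#' @param epochs,batch_size Training settings.
#' @return The [learned_recovery_experiment()] result list.
#' @export
recovery_study <- function(seed = 1, n_train = 40, n_test = 10,
                           epochs = 30, batch_size = 32) {
  train_scenes <- make_cohort(n_train, tone = rep(c("light", "dark"),
                                                  length.out = n_train),
                              seed = derive_seed(seed, 61))
  test_scenes <- make_cohort(n_test, tone = rep(c("light", "dark"),
                                                length.out = n_test),
                             seed = derive_seed(seed, 62))
  learned_recovery_experiment(
    train_scenes, test_scenes,
    model_cfg = experiment_model_config(),
    train_cfg = train_config(epochs = epochs, batch_size = batch_size,
                             seed = derive_seed(seed, 63)),
    stride = 128)
}

#' Skin-tone group study at the reference scale
#'
#' Learned-path group protocol on 24 light and 24 dark synthetic subjects:
#' within-group train/test splits plus both cross-tone scenarios. The two
#' cohorts are matched twins — identical respiratory rates, rate-variability
#' realizations and disturbance draws, differing only in the tone profile —
#' so tone-group comparisons are paired and the melanin effect is isolated
#' from between-subject physiological variability.
#'
#' @param seed Experiment seed.
#' @param n_per_group Subjects per tone group.
#' @param epochs Training epochs per group model.
#' @return Named list of [eval_report()]s (see [run_group_protocol()]).
#' @export
group_study <- function(seed = 1, n_per_group = 24, epochs = 20) {
  light <- make_cohort(n_per_group, tone = "light",
                       seed = derive_seed(seed, 51))
  dark <- make_cohort(n_per_group, tone = "dark",
                      seed = derive_seed(seed, 51))
  run_group_protocol(light, dark, path = "learned",
                     model_cfg = experiment_model_config(),
                     train_cfg = train_config(epochs = epochs, seed = seed),
                     stride = 128, test_frac = 0.4, seed = seed,
                     n_model_seeds = 2)
}

#' Channel SNR comparison across a cohort
#'
#' Mean spectral SNR (around each recording's true rate) of the chest-motion
#' and face-rPPG channels over a mixed-tone cohort.
#'
#' @param seed Experiment seed.
#' @param n Number of recordings.
#' @return List with `snr_chest_db`, `snr_face_db`, and per-recording values.
#' @export
snr_study <- function(seed = 1, n = 20) {
  scenes <- make_cohort(n, tone = rep(c("light", "dark"), length.out = n),
                        seed = derive_seed(seed, 71))
  chest <- numeric(n); face <- numeric(n)
  for (i in seq_len(n)) {
    b <- generate_channel_bundle(scenes[[i]])
    f0 <- scenes[[i]]$rr_bpm / 60
    chest[i] <- compute_snr(b$chest_motion, f0)
    face[i] <- compute_snr(b$face_rppg, f0)
  }
  list(snr_chest_db = mean(chest), snr_face_db = mean(face),
       chest = chest, face = face)
}

#' Camera-belt synchronization recovery
#'
#' Generates a recording with a known belt clock offset, derives the camera
#' signal from the chest motion channel, resamples and conditions the belt
#' trace, and recovers the offset by cross-correlation.
#'
#' @param seed Experiment seed.
#' @param offset_s Injected offset in seconds.
#' @return List with `recovered_lag_s`, `lag_samples`, `peak_corr`.
#' @export
sync_study <- function(seed = 1, offset_s = 0.5) {
  sc <- synthetic_scene(rr_bpm = 14, duration_s = 60,
                        belt_offset_s = offset_s, rr_var_bpm = 0.5,
                        seed = derive_seed(seed, 81))
  cam <- condition_signal(generate_channel_bundle(sc)$chest_motion)
  belt <- condition_signal(resample_signal(scene_belt_signal(sc), sc$fps))
  s <- synchronize(cam, belt)
  list(recovered_lag_s = s$lag_s, lag_samples = s$lag_samples,
       peak_corr = s$peak_corr)
}
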