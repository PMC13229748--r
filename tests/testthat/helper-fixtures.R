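# Shared fixtures: small scenes and a narrow network configuration so unit
# tests stay fast while exercising every architectural component.

quick_scene <- function(rr_bpm = 15, duration_s = 20, noise_sd = 0,
                        drift_amp = 0, seed = 1, ...) {
  synthetic_scene(rr_bpm = rr_bpm, duration_s = duration_s,
                  noise_sd = noise_sd, drift_amp = drift_amp,
                  seed = seed, ...)
}

tiny_model_config <- function(dropout = 0) {
  model_config(d_model = 8, conv_kernels = c(3, 3), n_heads = 2,
               lstm_layers = 2, lstm_hidden = 4,
               decoder_channels = c(4, 1), decoder_kernels = c(3, 1),
               dropout = dropout)
}

# Reduced-width configuration used for the synthetic training studies.
small_model_config <- function() {
  model_config(d_model = 16, n_heads = 2, lstm_hidden = 8,
               decoder_channels = c(8, 4, 1))
}

# Ground-truth facial ellipse mask of a scene (independent reconstruction
# from the scene geometry).
face_ellipse_mask <- function(sc) {
  H <- sc$frame_h; W <- sc$frame_w
  fb <- sc$face_box
  cx <- fb$x + fb$w / 2; cy <- fb$y + fb$h / 2
  cols <- matrix(rep(0:(W - 1), each = H), H, W)
  rows <- matrix(rep(0:(H - 1), W), H, W)
  (((cols + 0.5 - cx) / (fb$w / 2))^2 +
      ((rows + 0.5 - cy) / (fb$h / 2))^2 <= 1) * 1
}

# A tiny deterministic window set: 4-channel sinusoid bundle cut into
# windows, with the clean waveform as target.
tiny_training_set <- function(n_scenes = 2, win_len = 128, stride = 64,
                              seed = 5) {
  scenes <- make_cohort(n_scenes, tone = c("light", "dark"), seed = seed,
                        duration_s = 30)
  wins <- list(); targets <- list()
  for (sc in scenes) {
    b <- generate_channel_bundle(sc)
    pw <- prepare_windows(b, b$reference, win_len, stride)
    wins <- c(wins, pw$windows)
    targets <- c(targets, pw$targets)
  }
  list(windows = wins, targets = targets)
}
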