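# End-to-end pipelines: video -> four channels -> fused waveform -> RR, the
# window preparation for the learned path, and the study-level experiments
# (fusion-weight sweep, skin-tone group protocol).

#' Pipeline configuration defaults
#'
#' Central collection of every tunable, under namespaced keys. Values match
#' the printed design constants of the method (chest projection alpha 2.5 /
#' beta 0.2, 0.1-0.6 Hz order-4 band, 0.8/0.2 fusion, kernels 7/5/3, 8 heads,
#' AdamW with lr 0.001, batch 32, weight decay 1e-4).
#'
#' @return Nested list of configuration values.
#' @export
default_config <- function() {
  list(
    roi = list(alpha = 2.5, beta = 0.2, chest_mask = TRUE,
               blur_sigma = 1, open_radius = 1, close_radius = 1),
    smooth = list(sigma = 2, k = 6),
    filter = list(low_hz = 0.1, high_hz = 0.6, order = 4),
    fusion = list(w_chest = 0.8, w_face = 0.2),
    window = list(win_len = 256, stride = 32),
    flow = list(max_corners = 200, win = 15, levels = 3, iters = 3,
                redetect_below = 50),
    welch = list(seg_len = 512, overlap_frac = 0.5, window_fn = "hamming",
                 nfft = 8192),
    eval = list(max_lag_s = 10),
    seed = 1
  )
}

# Merge a partial user config into the defaults, rejecting unknown keys.
merge_config <- function(user, base = default_config()) {
  if (is.null(user)) return(base)
  for (nm in names(user)) {
    if (!nm %in% names(base)) stop("config error: unknown key '", nm, "'")
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(user[[nm]], base[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Extract the four channel signals from a video
#'
#' Per frame: detect the face (tracking by persistence on dropout), project
#' the chest box, build and refine the dual color-space skin mask per ROI,
#' photometrically normalize the ROI, and record the masked green mean
#' (rPPG). Motion signals come from pyramidal Lucas-Kanade tracking on
#' fixed-geometry grayscale crops (anchored at the first frame's boxes).
#' Temporal Gaussian smoothing is applied to the extracted rPPG traces
#' (equivalent, by linearity, to smoothing each pixel sequence first).
#'
#' @param source Frame source: a function `f(i)` with attribute `n_frames`
#'   (see [scene_frame_source()] or [read_video()]), or a list of frames.
#' @param fps Frame rate (taken from the source attribute when present).
#' @param detector Face detector, e.g. [oracle_face_detector()] or
#'   [skin_blob_face_detector()].
#' @param config Partial [default_config()] override.
#' @param motion_channels Which motion channels to compute (`"face"`,
#'   `"chest"`); the classical fused path needs only the chest motion.
#' @return List with the four [temporal_signal()]s (`face_rppg`,
#'   `face_motion`, `chest_rppg`, `chest_motion`; omitted motion channels are
#'   `NULL`) and the first-frame boxes.
#' @export
extract_channels <- function(source, fps = NULL, detector, config = NULL,
                             motion_channels = c("face", "chest")) {
  cfg <- merge_config(config)
  if (is.list(source)) {
    frames <- source
    n <- length(frames)
    get_frame <- function(i) frames[[i]]
    if (is.null(fps)) stop("invalid-parameter: fps required for a frame list")
  } else {
    get_frame <- source
    n <- attr(source, "n_frames")
    fps <- fps %||% attr(source, "fps")
  }
  thr <- skin_thresholds()
  face_vals <- numeric(n); chest_vals <- numeric(n)
  face_gray <- vector("list", n); chest_gray <- vector("list", n)
  prev_box <- NULL
  face0 <- NULL; chest0 <- NULL
  for (i in seq_len(n)) {
    frame <- get_frame(i)
    fh <- dim(frame)[1]; fw <- dim(frame)[2]
    fb <- detect_face(frame, detector, previous = prev_box)
    prev_box <- fb
    cb <- project_chest_roi(fb, cfg$roi$alpha, cfg$roi$beta, fw, fh)
    if (i == 1) { face0 <- fb; chest0 <- cb }
    roi_value <- function(box, use_mask) {
      crop <- crop_frame(frame, box)
      m <- combine_masks(skin_mask_ycrcb(crop, thr, i),
                         skin_mask_hsv(crop, thr, i))
      m <- refine_mask(m, cfg$roi$blur_sigma, cfg$roi$open_radius,
                       cfg$roi$close_radius)
      if (!use_mask) m$values[] <- 1
      idx <- m$values == 1
      if (sum(idx) < 2) return(NA_real_)
      # masked green mean of the photometrically normalized ROI; the mean of
      # (g - mu)/sd over the mask equals (mean(g) - mu)/sd, so the full
      # normalized array need not be materialized
      vals <- c(crop[, , 1][idx], crop[, , 2][idx], crop[, , 3][idx])
      mu <- mean(vals)
      sd_p <- sqrt(mean((vals - mu)^2))
      if (sd_p <= 0) return(NA_real_)
      (mean(crop[, , 2][idx]) - mu) / sd_p
    }
    face_vals[i] <- roi_value(fb, TRUE)
    chest_vals[i] <- roi_value(cb, cfg$roi$chest_mask)
    if ("face" %in% motion_channels) {
      face_gray[[i]] <- rgb_to_gray(crop_frame(frame, face0))
    }
    if ("chest" %in% motion_channels) {
      chest_gray[[i]] <- rgb_to_gray(crop_frame(frame, chest0))
    }
  }
  smooth <- function(v) temporal_gaussian_smooth(v, cfg$smooth$sigma, cfg$smooth$k)
  face_rppg <- fill_gaps_signal(face_vals, fps, "face_rppg")
  chest_rppg <- fill_gaps_signal(chest_vals, fps, "chest_rppg")
  face_rppg <- with_samples(face_rppg, smooth(face_rppg$samples))
  chest_rppg <- with_samples(chest_rppg, smooth(chest_rppg$samples))
  run_motion <- function(gray, label) {
    s <- extract_motion(gray, fps, cfg$flow$max_corners, cfg$flow$win,
                        cfg$flow$levels, cfg$flow$iters,
                        cfg$flow$redetect_below)
    with_samples(s, s$samples, label)
  }
  list(face_rppg = face_rppg,
       face_motion = if ("face" %in% motion_channels)
         run_motion(face_gray, "face_motion") else NULL,
       chest_rppg = chest_rppg,
       chest_motion = if ("chest" %in% motion_channels)
         run_motion(chest_gray, "chest_motion") else NULL,
       face_box = face0, chest_box = chest0)
}

#' Condition a raw channel signal for analysis
#'
#' The standard order: detrend, zero-phase Butterworth bandpass (0.1-0.6 Hz),
#' three-sigma normalization.
#'
#' @param signal A [temporal_signal()].
#' @param spec A [filter_spec()].
#' @return Conditioned [temporal_signal()].
#' @export
condition_signal <- function(signal, spec = filter_spec()) {
  three_sigma_normalize(bandpass_signal(detrend_signal(signal), spec))
}

#' Classical (non-learned) respiratory-rate estimate from channel signals
#'
#' Conditions the chest-motion and face-rPPG channels, fuses them with the
#' chest-dominant weights, and reads the respiratory rate off the Welch PSD
#' peak in the 0.1-0.6 Hz band.
#'
#' @param channels List with at least `chest_motion` and `face_rppg`
#'   [temporal_signal()]s (as returned by [extract_channels()] or
#'   [generate_channel_bundle()]).
#' @param w A [fusion_weights()].
#' @param spec A [filter_spec()].
#' @param params A [welch_params()].
#' @return A `spectral_estimate` with `rr_bpm`, plus the fused waveform under
#'   `$fused`.
#' @export
classical_rr <- function(channels, w = fusion_weights(),
                         spec = filter_spec(), params = welch_params()) {
  chest <- condition_signal(channels$chest_motion, spec)
  face <- condition_signal(channels$face_rppg, spec)
  fused <- fuse_signals(chest, face, w)
  # the channels are already detrended and bandpassed; re-filtering would
  # attenuate band-edge rates twice
  est <- estimate_rr(fused, params, postprocess = FALSE)
  est$fused <- fused
  est
}

#' Classical-path RR estimate for a rendered synthetic scene
#'
#' Renders the scene frame-by-frame (streaming), extracts the four channels
#' with the given detector (ground-truth oracle by default), and runs the
#' classical fused estimate.
#'
#' @param scene A [synthetic_scene()].
#' @param oracle Use the ground-truth face box detector (default) instead of
#'   the skin-blob detector.
#' @param config Partial configuration override.
#' @return List with `rr_bpm`, `estimate` (the `spectral_estimate`) and the
#'   extracted `channels`.
#' @export
classical_rr_from_scene <- function(scene, oracle = TRUE, config = NULL) {
  cfg <- merge_config(config)
  det <- if (oracle) oracle_face_detector(scene) else skin_blob_face_detector()
  src <- scene_frame_source(scene)
  ch <- extract_channels(src, detector = det, config = config,
                         motion_channels = "chest")
  est <- classical_rr(ch,
                      fusion_weights(cfg$fusion$w_chest, cfg$fusion$w_face),
                      filter_spec(cfg$filter$low_hz, cfg$filter$high_hz,
                                  cfg$filter$order),
                      welch_params(cfg$welch$seg_len, cfg$welch$overlap_frac,
                                   cfg$welch$window_fn, cfg$welch$nfft,
                                   c(cfg$filter$low_hz, cfg$filter$high_hz)))
  list(rr_bpm = est$rr_bpm, estimate = est, channels = ch)
}

#' Prepare model windows and aligned targets from channel signals
#'
#' Conditions each of the four channels, applies the region weighting as
#' channel scaling (chest channels x `w_chest`, face channels x `w_face`),
#' slices overlapping windows, and pairs each window with the aligned
#' conditioned reference waveform.
#'
#' @param channels List with the four channel [temporal_signal()]s.
#' @param reference Reference waveform [temporal_signal()] at the camera rate.
#' @param win_len,stride Window length and hop in frames.
#' @param w A [fusion_weights()] used for channel scaling.
#' @param spec A [filter_spec()].
#' @return List with `windows`, `targets`, `total_len`, `fs`.
#' @export
prepare_windows <- function(channels, reference, win_len = 256, stride = 32,
                            w = fusion_weights(), spec = filter_spec()) {
  cond <- lapply(channels[c("face_rppg", "face_motion",
                            "chest_rppg", "chest_motion")],
                 condition_signal, spec = spec)
  scale_ch <- c(w$w_face, w$w_face, w$w_chest, w$w_chest)
  for (j in seq_len(4)) {
    cond[[j]] <- with_samples(cond[[j]], cond[[j]]$samples * scale_ch[j])
  }
  wins <- make_windows(cond, win_len, stride)
  ref <- condition_signal(reference, spec)
  targets <- lapply(wins, function(wd) {
    ref$samples[(wd$start_index + 1):(wd$start_index + win_len)]
  })
  list(windows = wins, targets = targets,
       total_len = length(ref$samples), fs = reference$fs,
       reference = ref)
}

#' Build a cohort of synthetic scenes
#'
#' Subjects receive respiratory rates spread uniformly over the evaluated
#' 6-30 BPM range and cardiac rates over 60-90 BPM; each subject gets its own
#' derived seed.
#'
#' @param n Number of subjects.
#' @param tone Tone preset name (or vector recycled over subjects).
#' @param seed Cohort seed.
#' @param duration_s,fps Recording length and frame rate.
#' @param rr_var_bpm Within-recording rate variability; cohort recordings
#'   default to 0.75 BPM of natural breath-to-breath drift (a perfectly
#'   stationary scene is a controlled primitive, not a realistic subject).
#' @param ... Further arguments passed to [synthetic_scene()].
#' @return List of [synthetic_scene()]s with `subject_id` attributes.
#' @export
make_cohort <- function(n, tone = "light", seed = 1, duration_s = 60,
                        fps = 30, rr_var_bpm = 0.75, ...) {
  tones <- rep_len(tone, n)
  rates <- with_seed(derive_seed(seed, 13), stats::runif(n, 6, 30))
  hrs <- with_seed(derive_seed(seed, 17), stats::runif(n, 60, 90))
  lapply(seq_len(n), function(i) {
    sc <- synthetic_scene(rr_bpm = rates[i], hr_bpm = hrs[i],
                          tone = tones[i], duration_s = duration_s,
                          fps = fps, rr_var_bpm = rr_var_bpm,
                          seed = derive_seed(seed, 100 + i), ...)
    attr(sc, "subject_id") <- sprintf("s%03d", i)
    sc
  })
}

# Windows + targets for a list of scenes via the fast bundle path.
cohort_windows <- function(scenes, win_len, stride, w = fusion_weights(),
                           spec = filter_spec()) {
  wins <- list(); targets <- list(); subj <- character(0)
  per_scene <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    bundle <- generate_channel_bundle(scenes[[i]])
    pw <- prepare_windows(bundle, bundle$reference, win_len, stride, w, spec)
    per_scene[[i]] <- pw
    wins <- c(wins, pw$windows)
    targets <- c(targets, pw$targets)
    subj <- c(subj, rep(attr(scenes[[i]], "subject_id") %||% as.character(i),
                        length(pw$windows)))
  }
  list(windows = wins, targets = targets, subject = subj,
       per_scene = per_scene)
}

# Per-scene learned RR estimate: reconstruct the full waveform from window
# predictions and run the spectral estimator.
learned_rr_for_scene <- function(model, pw, welch = welch_params()) {
  pred <- predict_recording(model, pw$windows, pw$total_len)
  estimate_rr(pred, welch, postprocess = TRUE)$rr_bpm
}

#' Learned-path parameter-recovery experiment
#'
#' Trains the network on the channel bundles of a training cohort and
#' reports the RR error on held-out subjects: each test recording's windows
#' are predicted, overlap-averaged, post-processed and converted to BPM,
#' then compared with the true rate.
#'
#' @param train_scenes,test_scenes Cohorts from [make_cohort()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param win_len,stride Windowing for training and prediction.
#' @param val_frac Fraction of training windows used for validation.
#' @param verbose Print training progress.
#' @return List with `report` (an [eval_report()]), `model`, `ref`, `pred`.
#' @export
learned_recovery_experiment <- function(train_scenes, test_scenes,
                                        model_cfg = model_config(),
                                        train_cfg = train_config(),
                                        win_len = 256, stride = 128,
                                        val_frac = 0.1, verbose = FALSE) {
  tr <- cohort_windows(train_scenes, win_len, stride)
  n_val <- max(1, round(val_frac * length(tr$windows)))
  val_idx <- with_seed(derive_seed(train_cfg$seed, 19),
                       sample(seq_along(tr$windows), n_val))
  model <- train_model(tr$windows, tr$targets, model_cfg, train_cfg,
                       val_idx = val_idx, verbose = verbose)
  te <- cohort_windows(test_scenes, win_len, stride)
  pred <- vapply(te$per_scene, function(pw) learned_rr_for_scene(model, pw),
                 numeric(1))
  ref <- vapply(test_scenes, function(s) s$rr_bpm, numeric(1))
  list(report = eval_report(ref, pred, "held_out"), model = model,
       ref = ref, pred = pred)
}

#' Skin-tone group evaluation protocol
#'
#' Within-group scenarios train and test inside one tone group (subject-level
#' split); cross scenarios train on all of one group and test on all of the
#' other. The classical path skips training and evaluates every recording
#' directly.
#'
#' @param light_scenes,dark_scenes Cohorts from [make_cohort()] with the
#'   respective tone presets.
#' @param path `"learned"` or `"classical"`.
#' @param model_cfg,train_cfg Model/training configuration (learned path).
#' @param win_len,stride Windowing (learned path).
#' @param test_frac Held-out fraction for within-group evaluation.
#' @param seed Protocol seed.
#' @param n_model_seeds Number of paired training replicates per arm; the
#'   reported MAE/RMSE of each scenario is the mean over replicates, which
#'   suppresses training-stochasticity variance in the group comparison.
#' @return Named list of [eval_report()]s: `light`, `dark` (within-group) and
#'   for the learned path also `train_light_test_dark`,
#'   `train_dark_test_light`.
#' @export
run_group_protocol <- function(light_scenes, dark_scenes, path = "learned",
                               model_cfg = model_config(),
                               train_cfg = train_config(),
                               win_len = 256, stride = 128,
                               test_frac = 0.25, seed = 1,
                               n_model_seeds = 2) {
  if (length(light_scenes) == 0 || length(dark_scenes) == 0) {
    stop("invalid-parameter: both tone groups must be non-empty")
  }
  if (path == "classical") {
    rep_for <- function(scenes, label) {
      pred <- vapply(scenes, function(sc) {
        classical_rr(generate_channel_bundle(sc))$rr_bpm
      }, numeric(1))
      ref <- vapply(scenes, function(sc) sc$rr_bpm, numeric(1))
      eval_report(ref, pred, label)
    }
    return(list(light = rep_for(light_scenes, "light"),
                dark = rep_for(dark_scenes, "dark")))
  }
  split_group <- function(scenes, k) {
    n <- length(scenes)
    n_test <- max(1, round(test_frac * n))
    idx <- with_seed(derive_seed(seed, k), sample(n))
    list(train = scenes[idx[-seq_len(n_test)]],
         test = scenes[idx[seq_len(n_test)]])
  }
  # one split seed for both groups: with matched twin cohorts this keeps
  # train sets and test sets paired across tones, so the comparison
  # isolates the tone effect
  li <- split_group(light_scenes, 23)
  da <- split_group(dark_scenes, 23)
  train_on <- function(scenes, seed_shift) {
    tw <- cohort_windows(scenes, win_len, stride)
    tc <- train_cfg
    tc$seed <- derive_seed(train_cfg$seed, seed_shift)
    n_val <- max(1, round(0.1 * length(tw$windows)))
    val_idx <- with_seed(derive_seed(tc$seed, 19),
                         sample(seq_along(tw$windows), n_val))
    train_model(tw$windows, tw$targets, model_cfg, tc, val_idx = val_idx)
  }
  eval_on <- function(model, scenes, label) {
    tw <- cohort_windows(scenes, win_len, stride)
    pred <- vapply(tw$per_scene, function(pw) learned_rr_for_scene(model, pw),
                   numeric(1))
    ref <- vapply(scenes, function(s) s$rr_bpm, numeric(1))
    eval_report(ref, pred, label)
  }
  # identical training seeds for the two arms: with twin cohorts and a
  # shared split, initialization and batch order are then paired too, so
  # the only difference between the two trainings is the tone itself.
  # Averaging each scenario over several paired replicates suppresses the
  # remaining training-stochasticity variance.
  reps <- lapply(seq_len(n_model_seeds), function(k) {
    m_light <- train_on(li$train, 31 + 10 * k)
    m_dark <- train_on(da$train, 31 + 10 * k)
    list(
      light = eval_on(m_light, li$test, "light"),
      dark = eval_on(m_dark, da$test, "dark"),
      train_light_test_dark = eval_on(m_light, dark_scenes,
                                      "train_light_test_dark"),
      train_dark_test_light = eval_on(m_dark, light_scenes,
                                      "train_dark_test_light")
    )
  })
  if (n_model_seeds == 1) return(reps[[1]])
  avg <- function(nm) {
    rr <- do.call(c, lapply(reps, function(r) r[[nm]]$ref))
    pp <- do.call(c, lapply(reps, function(r) r[[nm]]$pred))
    eval_report(rr, pp, nm)
  }
  out <- lapply(names(reps[[1]]), avg)
  names(out) <- names(reps[[1]])
  out
}

#' Fusion-weight ablation sweep
#'
#' Re-runs the classical estimate over a grid of chest/face weights on a
#' cohort of synthetic recordings and reports the MAE per weight.
#'
#' @param scenes Cohort from [make_cohort()].
#' @param w_chest_grid Chest weights to evaluate.
#' @return Data frame with columns `w_chest`, `w_face`, `mae_bpm`.
#' @export
sweep_fusion_weights <- function(scenes,
                                 w_chest_grid = seq(0.5, 1.0, by = 0.1)) {
  bundles <- lapply(scenes, generate_channel_bundle)
  spec <- filter_spec()
  conds <- lapply(bundles, function(b) {
    list(chest = condition_signal(b$chest_motion, spec),
         face = condition_signal(b$face_rppg, spec))
  })
  ref <- vapply(scenes, function(s) s$rr_bpm, numeric(1))
  rows <- lapply(w_chest_grid, function(wc) {
    w <- fusion_weights(wc, 1 - wc)
    pred <- vapply(conds, function(cd) {
      estimate_rr(fuse_signals(cd$chest, cd$face, w),
                  postprocess = FALSE)$rr_bpm
    }, numeric(1))
    data.frame(w_chest = wc, w_face = 1 - wc, mae_bpm = mae(ref, pred))
  })
  do.call(rbind, rows)
}
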