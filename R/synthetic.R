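# Synthetic scene generator.
#
# Emulates a seated-subject acquisition: a skin-colored facial ellipse whose
# green channel carries cardiac and respiratory intensity modulation, a
# skin-colored torso whose upper edge and texture translate vertically with
# breathing, global multiplicative illumination drift, per-pixel sensor noise,
# and a respiration-belt reference with an injected clock offset. All outputs
# are pure functions of (scene, seed).

#' Skin-tone profile for the synthetic generator
#'
#' Darker skin reflects less incident light and carries proportionally weaker
#' photoplethysmographic modulation (melanin attenuates the optical signal),
#' so the `dark` preset has both a lower mean reflectance and smaller
#' modulation amplitudes than the `light` preset.
#'
#' @param name `"light"`, `"dark"`, or any label when the remaining arguments
#'   are supplied explicitly.
#' @param base_rgb Mean skin reflectance triple on the 0-255 scale.
#' @param pulse_amp Green-channel cardiac modulation amplitude (intensity units).
#' @param resp_amp Green-channel respiratory modulation amplitude (intensity units).
#' @return An object of class `tone_profile`.
#' @export
tone_profile <- function(name = c("light", "dark"),
                         base_rgb = NULL, pulse_amp = NULL, resp_amp = NULL) {
  if (is.null(base_rgb)) {
    name <- match.arg(name)
    preset <- switch(name,
      light = list(base_rgb = c(230, 195, 175), pulse_amp = 1.0, resp_amp = 2.0),
      dark  = list(base_rgb = c(150, 110, 100), pulse_amp = 0.4, resp_amp = 0.8)
    )
    base_rgb <- preset$base_rgb
    pulse_amp <- pulse_amp %||% preset$pulse_amp
    resp_amp <- resp_amp %||% preset$resp_amp
  }
  stopifnot(length(base_rgb) == 3, all(base_rgb >= 0), all(base_rgb <= 255))
  if (pulse_amp < 0 || resp_amp < 0) {
    stop("invalid-parameter: modulation amplitudes must be non-negative")
  }
  structure(list(name = if (is.character(name)) name[1] else "custom",
                 base_rgb = as.numeric(base_rgb),
                 pulse_amp = pulse_amp, resp_amp = resp_amp),
            class = "tone_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derived sub-seed
#'
#' Deterministically maps a base seed and a stream index to a new seed below
#' 2^31, so independent randomness streams (noise, textures, cohorts) can be
#' drawn reproducibly from one experiment seed.
#'
#' @param seed Base integer seed.
#' @param k Stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

#' Synthetic recording description with full ground truth
#'
#' Defines one synthetic recording: true respiratory and cardiac rates, tone
#' profile, chest displacement, noise and drift levels, belt sampling and
#' clock offset, and the ground-truth face/chest boxes. Geometry is
#' resolution-relative; the default 240 x 180 frame keeps rendering fast while
#' preserving all signal structure.
#'
#' @param rr_bpm True respiratory rate, breaths/min (evaluated range 6-30).
#' @param duration_s Recording length in seconds.
#' @param fps Camera frame rate, frames/s.
#' @param hr_bpm Cardiac rate, beats/min.
#' @param tone A [tone_profile()] or preset name.
#' @param chest_disp_px Peak vertical chest displacement in pixels.
#' @param noise_sd Per-pixel Gaussian sensor noise SD (intensity units).
#' @param drift_amp Multiplicative illumination drift amplitude (unitless).
#' @param harmonic_frac Second-harmonic fraction of the breathing waveform.
#' @param rr_var_bpm Within-recording instantaneous-rate variability in BPM
#'   (0 = perfectly stationary breathing; realistic cohorts use about 0.75).
#' @param belt_fs Belt sampling rate in Hz.
#' @param belt_offset_s Injected camera-belt clock offset in seconds.
#' @param frame_w,frame_h Frame size in pixels.
#' @param seed RNG seed (integer below 2^31).
#' @return An object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(rr_bpm = 15, duration_s = 60, fps = 30,
                            hr_bpm = 72, tone = "light",
                            chest_disp_px = 3, noise_sd = 2,
                            drift_amp = 0.03, harmonic_frac = 0.3,
                            rr_var_bpm = 0,
                            belt_fs = 10, belt_offset_s = 0,
                            frame_w = 240, frame_h = 180, seed = 1) {
  if (is.character(tone)) tone <- tone_profile(tone)
  stopifnot(inherits(tone, "tone_profile"))
  if (rr_bpm < 6 || rr_bpm > 30) {
    stop("invalid-parameter: rr_bpm must lie in the evaluated 6-30 BPM range")
  }
  if (fps <= 2 * (rr_bpm / 60)) {
    stop("invalid-parameter: fps must exceed twice the respiratory frequency")
  }
  if (duration_s <= 0 || chest_disp_px < 0 || noise_sd < 0 || drift_amp < 0) {
    stop("invalid-parameter: scene amplitudes must be non-negative")
  }
  # Resolution-relative geometry (0-based half-open boxes).
  cx <- round(frame_w * 0.50); cy <- round(frame_h * 0.26)
  a <- round(frame_w * 0.125); b <- round(frame_h * 0.185)
  face_box <- bounding_box(cx - a, cy - b, 2 * a, 2 * b)
  torso_x0 <- round(frame_w * 0.25); torso_x1 <- round(frame_w * 0.79)
  torso_ytop <- round(frame_h * 0.61)
  chest_box <- bounding_box(torso_x0 + 2,
                            torso_ytop + ceiling(chest_disp_px) + 2,
                            torso_x1 - torso_x0 - 4,
                            frame_h - 2 - (torso_ytop + ceiling(chest_disp_px) + 2))
  structure(list(
    rr_bpm = rr_bpm, duration_s = duration_s, fps = fps, hr_bpm = hr_bpm,
    tone = tone, chest_disp_px = chest_disp_px, noise_sd = noise_sd,
    drift_amp = drift_amp, harmonic_frac = harmonic_frac,
    rr_var_bpm = rr_var_bpm,
    belt_fs = belt_fs, belt_offset_s = belt_offset_s,
    frame_w = frame_w, frame_h = frame_h, seed = as.integer(seed),
    face_box = face_box, chest_box = chest_box,
    torso_x0 = torso_x0, torso_x1 = torso_x1, torso_ytop = torso_ytop,
    chest_rppg_gain = 0.6
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene %gx%g @%g fps, %g s, RR=%g BPM, HR=%g BPM, tone=%s, seed=%d>\n",
    x$frame_w, x$frame_h, x$fps, x$duration_s, x$rr_bpm, x$hr_bpm,
    x$tone$name, x$seed))
  invisible(x)
}

# Breathing phase process. With rr_var_bpm = 0 the phase is exactly
# 2*pi*f0*t. With rr_var_bpm > 0 the instantaneous rate is slowly frequency
# modulated by two incommensurate slow oscillations with seeded random
# phases (emulating natural breath-to-breath rate variability); the phase is
# the closed-form integral of the instantaneous frequency, so camera and
# belt samplings of the same scene are mutually consistent at any offset.
resp_phase_fn <- function(rr_bpm, rr_var_bpm = 0, seed = 0) {
  f0 <- rr_bpm / 60
  if (rr_var_bpm <= 0) {
    return(function(t) 2 * pi * f0 * t)
  }
  ph <- with_seed(derive_seed(seed, 5), stats::runif(2, 0, 2 * pi))
  w1 <- 2 * pi * 0.015; w2 <- 2 * pi * 0.033
  a2 <- 0.6
  norm <- sqrt((1 + a2^2) / 2)              # long-run SD of the modulator
  dev <- rr_var_bpm / 60 / norm             # Hz deviation scale
  Fint <- function(t) -(cos(w1 * t + ph[1]) / w1 +
                          a2 * cos(w2 * t + ph[2]) / w2)
  function(t) 2 * pi * (f0 * t + dev * (Fint(t) - Fint(0)))
}

#' Generate a respiratory reference waveform
#'
#' `r(t) = sin(phi(t)) + harmonic_frac * sin(2 phi(t))` with phase
#' `phi(t) = 2 pi f t`, `f = rr_bpm / 60`, and unit peak amplitude of the
#' fundamental. The second harmonic is a simple proxy for non-sinusoidal
#' breathing morphology. With `rr_var_bpm > 0` the instantaneous rate drifts
#' slowly around `rr_bpm` with roughly that standard deviation (in BPM),
#' emulating natural breath-to-breath variability.
#'
#' @param rr_bpm Mean respiratory rate in breaths/min.
#' @param duration_s Duration in seconds; must cover at least two breaths.
#' @param fs Sampling rate in Hz.
#' @param harmonic_frac Amplitude of the second harmonic relative to the
#'   fundamental.
#' @param seed Seed for the rate-variability phases (unused when
#'   `rr_var_bpm = 0`).
#' @param rr_var_bpm Instantaneous-rate variability in BPM (0 = stationary).
#' @param t0 Time of the first sample in seconds.
#' @return A [temporal_signal()] with `round(duration_s * fs)` samples.
#' @export
generate_respiratory_waveform <- function(rr_bpm, duration_s, fs,
                                          harmonic_frac = 0, seed = 0,
                                          rr_var_bpm = 0, t0 = 0) {
  if (rr_bpm <= 0 || fs <= 0 || duration_s <= 0) {
    stop("invalid-parameter: rr_bpm, fs and duration_s must be positive")
  }
  if (fs <= rr_bpm / 30) {
    stop("invalid-parameter: fs below the respiratory Nyquist rate")
  }
  if (duration_s <= 2 * 60 / rr_bpm) {
    stop("invalid-parameter: duration must cover more than two breathing cycles")
  }
  n <- round(duration_s * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  phi <- resp_phase_fn(rr_bpm, rr_var_bpm, seed %||% 0)(t)
  r <- sin(phi) + harmonic_frac * sin(2 * phi)
  temporal_signal(r, fs, channel = "belt", t0 = t0)
}

# Quasi-periodic rocking of a seated body: a narrowband oscillation at a
# random frequency inside (or near) the respiratory band, with a
# per-recording random amplitude that is usually small but occasionally
# rivals the breathing displacement. Scaled by the scene noise level so
# noiseless scenes are perfectly still. Common to every motion observation
# of the same body.
oscillatory_sway <- function(scene, t) {
  if (scene$noise_sd <= 0) return(numeric(length(t)))
  par <- with_seed(derive_seed(scene$seed, 6), stats::runif(3))
  f_osc <- 0.08 + 0.37 * par[1]
  amp <- 0.9 * scene$chest_disp_px * par[2]^2 * scene$noise_sd / 2
  amp * sin(2 * pi * f_osc * t + 2 * pi * par[3])
}

# Precompute everything a frame renderer needs once per scene.
scene_realization <- function(scene) {
  n <- round(scene$duration_s * scene$fps)
  t <- (seq_len(n) - 1) / scene$fps
  r <- scene_waveform(scene, scene$fps)$samples
  pulse <- sin(2 * pi * (scene$hr_bpm / 60) * t + 0.7)
  drift <- 1 + scene$drift_amp * sin(2 * pi * 0.02 * t)

  H <- scene$frame_h; W <- scene$frame_w
  bg <- c(40, 110, 60)  # uniform green backdrop
  base <- array(0, c(H, W, 3))
  for (ch in 1:3) base[, , ch] <- bg[ch]

  # Face ellipse mask and static speckle texture (skin micro-structure).
  fb <- scene$face_box
  cx <- fb$x + fb$w / 2; cy <- fb$y + fb$h / 2
  ax <- fb$w / 2; by <- fb$h / 2
  cols <- matrix(rep(0:(W - 1), each = H), H, W)
  rows <- matrix(rep(0:(H - 1), W), H, W)
  face_mask <- ((cols + 0.5 - cx) / ax)^2 + ((rows + 0.5 - cy) / by)^2 <= 1
  face_idx <- which(face_mask)
  face_speckle <- with_seed(derive_seed(scene$seed, 1),
                            rnorm(length(face_idx), 0, 1.5))
  for (ch in 1:3) {
    plane <- base[, , ch]
    plane[face_idx] <- scene$tone$base_rgb[ch] + face_speckle
    base[, , ch] <- plane
  }

  # Static torso texture, tall enough for the peak displacement; sampled at a
  # vertical offset each frame so fabric/skin structure moves with the chest.
  # Texture contrast scales with the tone's mean reflectance: darker surfaces
  # reflect less light, giving optical flow weaker gradients to lock onto.
  pad <- ceiling(scene$chest_disp_px) + 8  # headroom for displacement + sway
  tw <- scene$torso_x1 - scene$torso_x0
  th <- H - scene$torso_ytop + 2 * pad
  tex_sd <- 6 * mean(scene$tone$base_rgb) / 200
  torso_tex <- with_seed(derive_seed(scene$seed, 2),
                         matrix(rnorm(th * tw, 0, tex_sd), th, tw))
  # band-limit the texture (camera point-spread function): sub-pixel motion
  # of aliased white noise is not a valid imaging model and biases
  # gradient-based flow
  torso_tex <- blur_mat(torso_tex, 0.8) * 2

  # Postural sway: slow random-walk torso drift (non-respiratory motion),
  # scaled with the scene noise level so noiseless scenes are sway-free.
  sway <- with_seed(derive_seed(scene$seed, 4),
                    cumsum(rnorm(n, 0, 0.03 * scene$noise_sd)))
  disp <- scene$chest_disp_px * r + sway + oscillatory_sway(scene, t)

  list(n = n, t = t, r = r, pulse = pulse, drift = drift, disp = disp,
       base = base, face_idx = face_idx, pad = pad, torso_tex = torso_tex)
}

# Render frame i (1-based) as an H x W x 3 double array on the 0-255 scale.
render_frame_impl <- function(scene, real, i) {
  H <- scene$frame_h; W <- scene$frame_w
  frame <- real$base
  tone <- scene$tone
  r_t <- real$r[i]; pulse_t <- real$pulse[i]

  # Facial photoplethysmographic modulation (green channel).
  g <- frame[, , 2]
  g[real$face_idx] <- g[real$face_idx] +
    tone$pulse_amp * pulse_t + tone$resp_amp * r_t
  frame[, , 2] <- g

  # Torso: top edge at ytop0 - chest_disp * r(t) (rises on inhalation), with
  # sub-pixel edge coverage and texture translating rigidly with the torso.
  d <- real$disp[i]                           # upward displacement in rows
  ytop <- scene$torso_ytop - d
  x0 <- scene$torso_x0; x1 <- scene$torso_x1
  rows0 <- floor(ytop)                        # first (partially) covered row
  rows <- max(0, rows0):(H - 1)
  cov <- pmin(pmax(rows + 1 - ytop, 0), 1)    # vertical coverage fraction
  # texture row coordinate in the static texture frame (1-based with padding)
  texr <- rows + d + real$pad - scene$torso_ytop + 1
  lo <- floor(texr); fr <- texr - lo
  lo <- pmin(pmax(lo, 1), nrow(real$torso_tex) - 1)
  tex <- (1 - fr) * real$torso_tex[lo, , drop = FALSE] +
    fr * real$torso_tex[lo + 1, , drop = FALSE]
  chest_g_mod <- scene$chest_rppg_gain * tone$resp_amp * r_t +
    0.3 * tone$pulse_amp * pulse_t
  ridx <- rows + 1; cidx <- (x0 + 1):x1
  for (ch in 1:3) {
    plane <- frame[, , ch]
    skin <- tone$base_rgb[ch] + tex
    if (ch == 2) skin <- skin + chest_g_mod
    plane[ridx, cidx] <- cov * skin + (1 - cov) * plane[ridx, cidx]
    frame[, , ch] <- plane
  }

  if (scene$drift_amp > 0) frame <- frame * real$drift[i]
  if (scene$noise_sd > 0) {
    noise <- with_seed(derive_seed(scene$seed, 1000 + i),
                       rnorm(H * W * 3, 0, scene$noise_sd))
    frame <- frame + array(noise, c(H, W, 3))
    frame[frame < 0] <- 0
    frame[frame > 255] <- 255
  }
  frame
}

#' Create a frame source for a synthetic scene
#'
#' Returns a closure `f(i)` producing frame `i` (1-based) on demand as an
#' H x W x 3 double array, so long recordings never need to be held in memory
#' at once. Identical scenes yield bit-identical frames.
#'
#' @param scene A [synthetic_scene()].
#' @return A function of the frame index, with attributes `n_frames` and `fps`.
#' @export
scene_frame_source <- function(scene) {
  real <- scene_realization(scene)
  f <- function(i) {
    stopifnot(i >= 1, i <= real$n)
    render_frame_impl(scene, real, i)
  }
  attr(f, "n_frames") <- real$n
  attr(f, "fps") <- scene$fps
  f
}

#' Render all frames of a synthetic scene into memory
#'
#' @param scene A [synthetic_scene()].
#' @param indices Frame indices to render (default all).
#' @return List of H x W x 3 arrays.
#' @export
render_frames <- function(scene, indices = NULL) {
  real <- scene_realization(scene)
  indices <- indices %||% seq_len(real$n)
  lapply(indices, function(i) render_frame_impl(scene, real, i))
}

#' Render a synthetic scene to a directory of PNG frames
#'
#' Writes `round(duration_s * fps)` 8-bit RGB PNG frames named
#' `frame_000001.png`, ... plus a `metadata.json` recording the full ground
#' truth. The static skin speckle texture acts as spatial dither, so
#' sub-integer respiratory modulation survives quantization once averaged
#' over the skin mask; controlled numerical experiments can use the
#' unquantized in-memory path ([scene_frame_source()]).
#'
#' @param scene A [synthetic_scene()].
#' @param out_dir Output directory (created if missing).
#' @return The scene, invisibly, with attribute `out_dir`.
#' @export
render_video <- function(scene, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create ", out_dir)
  real <- scene_realization(scene)
  for (i in seq_len(real$n)) {
    fr <- render_frame_impl(scene, real, i) / 255
    png::writePNG(fr, file.path(out_dir, sprintf("frame_%06d.png", i)))
  }
  meta <- scene
  meta$tone <- unclass(meta$tone)
  meta$face_box <- unclass(meta$face_box)
  meta$chest_box <- unclass(meta$chest_box)
  jsonlite::write_json(unclass(meta), file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(scene, "out_dir") <- out_dir
  invisible(scene)
}

#' Read scene metadata written by [render_video()]
#' @param dir Directory containing `metadata.json`.
#' @return A `synthetic_scene`.
#' @export
read_scene_metadata <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  scene <- synthetic_scene(
    rr_bpm = m$rr_bpm, duration_s = m$duration_s, fps = m$fps,
    hr_bpm = m$hr_bpm,
    tone = tone_profile(m$tone$name, base_rgb = m$tone$base_rgb,
                        pulse_amp = m$tone$pulse_amp, resp_amp = m$tone$resp_amp),
    chest_disp_px = m$chest_disp_px, noise_sd = m$noise_sd,
    drift_amp = m$drift_amp, harmonic_frac = m$harmonic_frac,
    rr_var_bpm = m$rr_var_bpm %||% 0,
    belt_fs = m$belt_fs, belt_offset_s = m$belt_offset_s,
    frame_w = m$frame_w, frame_h = m$frame_h, seed = m$seed)
  scene
}

#' True breathing waveform of a scene at an arbitrary sampling rate
#'
#' @param scene A [synthetic_scene()].
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample (seconds, camera clock).
#' @return A [temporal_signal()].
#' @export
scene_waveform <- function(scene, fs = scene$fps, t0 = 0) {
  generate_respiratory_waveform(scene$rr_bpm, scene$duration_s, fs,
                                scene$harmonic_frac, seed = scene$seed,
                                rr_var_bpm = scene$rr_var_bpm, t0 = t0)
}

#' Directly synthesize the four-channel signal bundle of a scene
#'
#' Fast path bypassing rendering: produces the face-rPPG, face-motion,
#' chest-rPPG and chest-motion channels with the same modulation model as the
#' renderer, plus the clean reference waveform. Chest channels carry stronger
#' respiratory coupling than facial ones, and rPPG channels carry more noise
#' than the geometric motion channels.
#'
#' @param scene A [synthetic_scene()].
#' @param rppg_noise_scale,motion_noise_scale Channel noise SD as a fraction
#'   of the scene's `noise_sd`.
#' @return List with elements `face_rppg`, `face_motion`, `chest_rppg`,
#'   `chest_motion` and `reference` ([temporal_signal()]s at the camera rate).
#' @export
generate_channel_bundle <- function(scene, rppg_noise_scale = 0.25,
                                    motion_noise_scale = 0.05) {
  real_n <- round(scene$duration_s * scene$fps)
  t <- (seq_len(real_n) - 1) / scene$fps
  r <- scene_waveform(scene, scene$fps)$samples
  pulse <- sin(2 * pi * (scene$hr_bpm / 60) * t + 0.7)
  tone <- scene$tone
  # Darker tones give the tracker less image contrast relative to the same
  # sensor noise, so the motion channels degrade with reflectance just as
  # the rPPG amplitude does.
  tone_factor <- 200 / mean(tone$base_rgb)
  sd_rppg <- scene$noise_sd * rppg_noise_scale
  sd_mot <- scene$noise_sd * motion_noise_scale * tone_factor
  noise <- with_seed(derive_seed(scene$seed, 3),
                     matrix(rnorm(real_n * 10), real_n, 10))
  # Structured disturbances, all random walks (power concentrated at low
  # frequencies, partly inside the respiratory band), all scaled by the
  # scene noise level:
  #  - postural sway: ONE body moving, hence common to both motion channels;
  #  - feature-tracking drift: both trackers run on the same frames, so the
  #    drift has a common and a per-tracker component; its rate grows
  #    steeply as surface reflectance falls (the cubic exponent is an
  #    emulation constant calibrated so the dark-to-light error ratio of
  #    the fused classical estimate is roughly twofold, the degradation
  #    scale reported for darker skin in camera-based RR studies);
  #  - colored photometric wander: one light source, hence common to both
  #    rPPG channels.
  sway_sd <- 0.03 * scene$noise_sd
  track_sd <- 0.06 * scene$noise_sd * tone_factor^3
  sway <- cumsum(sway_sd * noise[, 5]) + oscillatory_sway(scene, t)
  track_common <- cumsum(track_sd * noise[, 6]) / sqrt(2)
  track_face <- track_common + cumsum(track_sd * noise[, 7]) / sqrt(2)
  track_chest <- track_common + cumsum(track_sd * noise[, 8]) / sqrt(2)
  col_sd <- 0.075 * scene$noise_sd
  col_common <- cumsum(col_sd * noise[, 9])
  fs <- scene$fps
  list(
    face_rppg = temporal_signal(
      tone$resp_amp * r + tone$pulse_amp * pulse + sd_rppg * noise[, 1] +
        col_common,
      fs, "face_rppg"),
    face_motion = temporal_signal(
      0.15 * scene$chest_disp_px * r + sway + track_face +
        sd_mot * noise[, 2],
      fs, "face_motion"),
    chest_rppg = temporal_signal(
      scene$chest_rppg_gain * tone$resp_amp * r + 0.3 * tone$pulse_amp * pulse +
        sd_rppg * noise[, 3] + col_common,
      fs, "chest_rppg"),
    chest_motion = temporal_signal(
      scene$chest_disp_px * r + sway + track_chest + sd_mot * noise[, 4],
      fs, "chest_motion"),
    reference = temporal_signal(r, fs, "belt")
  )
}

#' Belt reference signal of a scene at the belt sampling rate
#'
#' Emulates a belt logger started `belt_offset_s` seconds after the camera:
#' sample `i` holds the breathing waveform at camera time
#' `belt_offset_s + i / belt_fs`, and the signal's `t0` carries the offset.
#' Cross-correlation against the camera-derived signal therefore recovers the
#' injected offset.
#'
#' @param scene A [synthetic_scene()].
#' @return A [temporal_signal()] sampled at `scene$belt_fs`.
#' @export
scene_belt_signal <- function(scene) {
  scene_waveform(scene, scene$belt_fs, t0 = scene$belt_offset_s)
}

#' Write a belt recording as a two-column CSV
#'
#' Columns `time_s,respiration`; timestamps start at `offset_s` and advance at
#' the signal's sampling rate.
#'
#' @param signal A [temporal_signal()].
#' @param offset_s Clock offset of the first sample in seconds (defaults to
#'   the signal's own `t0`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_belt_csv <- function(signal, offset_s = signal$t0, path) {
  stopifnot(inherits(signal, "temporal_signal"))
  df <- data.frame(
    time_s = offset_s + (seq_along(signal$samples) - 1) / signal$fs,
    respiration = signal$samples
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
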