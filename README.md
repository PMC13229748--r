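# respcam

Non-contact respiratory rate (RR) estimation from RGB video, with a
skin-tone-aware synthetic benchmark generator.

A camera sees two independent signatures of breathing: a sub-percent
modulation of skin reflectance (remote photoplethysmography, rPPG) and a
millimeter-scale vertical chest translation. `respcam` implements the full
pipeline from video to breaths per minute:

1. **Region extraction** — pluggable face detection (Haar rectangle
   primitive included; oracle detector for synthetic scenes; skin-blob
   detector for plain frames), geometric chest projection
   (`y ∈ [y+h, y+αh)`, `x ∈ [x−βw, x+(1+β)w)` with `α = 2.5`, `β = 0.2`),
   and dual color-space skin masks (Cr ∈ [133,173] ∧ Cb ∈ [77,127]) ∨
   (H ∈ [0,50] ∧ S ∈ [58,174]) refined by Gaussian blur and morphological
   opening/closing.
2. **Signal extraction** — per-frame masked green means (rPPG) after joint
   photometric normalization `(I − μ_f)/σ_f`; chest motion via pyramidal
   Lucas–Kanade optical flow with bottom-weighted vertical components;
   temporal Gaussian smoothing.
3. **Conditioning** — detrend → zero-phase 4th-order Butterworth bandpass
   (0.1–0.6 Hz) → three-sigma normalization `(x − μ)/(3σ)`.
4. **Waveform reconstruction** — classical chest-dominant fusion
   `S(t) = 0.8 S_chest(t) + 0.2 S_face(t)`, or a hybrid network
   (per-timestep embedding → three 1-D conv blocks with kernels 7/5/3 →
   8-head self-attention with residual + layer norm → two-layer BiLSTM →
   conv decoder 64/32/1) trained with AdamW (lr 0.001, weight decay 1e-4,
   batch 32, reduce-on-plateau), implemented natively in R with
   finite-difference-verified backpropagation.
5. **Rate estimation** — Welch PSD (Hamming taper, 50% overlap, zero-padded
   grid ≈ 0.22 BPM/bin), `RR = 60 · argmax P(f)` over 0.1–0.6 Hz.
6. **Evaluation** — camera–belt synchronization by normalized
   cross-correlation, MAE/RMSE, Bland–Altman limits of agreement, Pearson
   correlation, and a matched-twin skin-tone group protocol.

Because real recordings of this kind are not redistributable, the package
ships a fully seeded synthetic generator (`synthetic_scene`,
`render_video`, `generate_channel_bundle`) that emulates the acquisition —
tone-dependent rPPG amplitudes, breathing-driven chest translation with
sub-pixel motion, rate variability, postural sway and rocking, colored
photometric wander, tracking drift, sensor noise, and an offset belt
reference — so every stage is testable end to end with known ground truth.

## Worked example

```r
library(respcam)

# a 60-s synthetic recording: dark skin tone, true RR 17 BPM with natural
# breath-to-breath variability
scene <- synthetic_scene(rr_bpm = 17, tone = "dark", rr_var_bpm = 0.75,
                         seed = 11)
bundle <- generate_channel_bundle(scene)

est <- classical_rr(bundle)
round(est$rr_bpm, 2)
#> [1] 16.7

round(est$f_peak, 4)
#> [1] 0.2783

# chest motion carries the stronger respiratory signal
round(compute_snr(bundle$chest_motion, 17 / 60), 1)
#> [1] -3.7
round(compute_snr(bundle$face_rppg, 17 / 60), 1)
#> [1] -6

# agreement over a small mixed-tone cohort
scenes <- make_cohort(8, tone = rep(c("light", "dark"), 4), seed = 7)
ref <- sapply(scenes, function(s) s$rr_bpm)
pred <- sapply(scenes, function(s) classical_rr(generate_channel_bundle(s))$rr_bpm)
eval_report(ref, pred, "all")
#> <eval_report 'all': n=8, MAE=0.245, RMSE=0.265 BPM, bias=-0.015, LoA=[-0.57, 0.54], r=0.999>
```

The estimate lands within a fraction of a breath per minute of the true
rate; the Bland–Altman limits and correlation summarize agreement across
the cohort the way a clinical validation would report it.

The same pipeline runs on rendered video (`render_video(scene, dir)` then
`classical_rr_from_scene(scene)` or the command-line tool in
`inst/cli/respcam`: `respcam synth`, `respcam estimate`, `respcam
sweep-fusion`, ...). Training and evaluation of the network are exposed
through `train_model()`, `predict_recording()`, `run_group_protocol()` and
the study wrappers in `?recovery_study`.

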