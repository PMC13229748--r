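---
title: "Camera-based respiratory rate estimation: models, parameters and design choices"
author: "respcam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based respiratory rate estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Respiratory rate (RR) is one of the most sensitive early indicators of
cardiorespiratory deterioration, yet the standard instruments (belts,
spirometry, capnography) are contact-based. A plain RGB camera observes two
independent physical signatures of breathing: a sub-percent modulation of
skin reflectance tied to blood-volume changes (remote photoplethysmography,
rPPG) and a millimeter-scale vertical translation of the chest wall. Both
live in the 0.1–0.6 Hz band (6–36 breaths/min). The central difficulty is
that the optical signature weakens substantially with increasing melanin
concentration, so naive rPPG pipelines systematically underperform on
darker skin tones.

`respcam` implements a dual-region, dual-modality pipeline: face and chest
regions are detected and skin-masked per frame; an rPPG trace and an
optical-flow motion trace are extracted from each region; the four channels
are conditioned and either fused classically (chest-dominant weighted sum)
or mapped to a respiratory waveform by a hybrid
convolution–attention–BiLSTM network; the rate is the dominant in-band peak
of the Welch power spectral density of that waveform.

## Region extraction

Face detection is pluggable. For synthetic recordings an oracle detector
returns the generator's ground-truth box, isolating downstream stages from
detection error. For plain frames a skin-blob detector segments skin pixels
and returns the topmost sufficiently large connected component (a seated
subject's face lies above the chest). The Haar rectangle-difference
primitive that underlies cascade detectors is provided (`haar_feature`) and
verified against brute-force summation; shipping or training a full cascade
is out of scope. When several candidate boxes appear, the largest area wins
(single-subject assumption); when a frame yields no detection, the previous
frame's box is reused, and a failure on the very first frame is a hard
error.

The chest box is projected from the face box: vertically from the bottom of
the face to `alpha` face-heights below its top (`alpha = 2.5`), horizontally
widened by `beta = 0.2` face-widths per side, then clipped to the frame.
These proportions consistently cover the upper thorax across body sizes.

Skin segmentation combines two color-space tests with an OR: chrominance
bounds in YCrCb (Cr in [133, 173], Cb in [77, 127], full-range 8-bit JPEG
convention) and hue/saturation bounds in HSV (H in [0, 50], S in [58, 174]
on a 0–255 scale where the full hue circle maps to 255). These are widely
used skin-detection ranges; all eight bounds are configurable
(`skin_thresholds()`). The mask is refined by Gaussian blur (sigma 1 px),
re-thresholding at 0.5, then morphological opening and closing with disc
elements of radius 1 — speckle noise is removed and pinholes filled while
region boundaries move by at most the disc radius. The chest region is
skin-masked identically to the face by default; `roi$chest_mask = FALSE`
disables this for clothed-torso footage where masking would reject the
informative region.

## Preprocessing

Each pixel-intensity sequence is smoothed with a truncated Gaussian kernel,
normalized to unit sum so constants pass unchanged. Defaults sigma = 2
frames, half-width k = 6 place the −3 dB point far above 0.6 Hz at 30 fps
(the gain at 0.3 Hz exceeds 0.97), so respiratory content is preserved
while flicker and sensor noise are attenuated. Because the smoother is
linear and the rPPG signal is a spatial mean, smoothing the per-frame mean
trace is mathematically identical to smoothing every pixel sequence first;
the pipeline uses this fast equivalent, and the equivalence is asserted in
the tests. Boundaries are handled by reflection.

Per-frame photometric normalization standardizes all masked pixel values
(all channels jointly) to zero mean and unit population SD. Joint
normalization cancels multiplicative illumination drift while leaving the
green-specific respiratory modulation in place, and brings subjects of
different mean reflectance onto one scale. A frame whose mask has fewer
than two pixels or zero variance raises a `degenerate-frame` condition; the
pipeline records the frame as missing and fills it by linear interpolation.

## Signal extraction and conditioning

The rPPG trace is the masked green-channel mean per frame — green carries
the strongest blood-volume signature. Motion is tracked with a pyramidal
Lucas–Kanade flow: Shi–Tomasi corners (up to 200, re-detected when fewer
than 50 survive), 15×15 integration windows, 3 pyramid levels, iterative
refinement with bilinear warping. Per frame the signal is a weighted mean
of vertical flow components, with weights rising linearly from 0.2 at the
top of the ROI to 1.0 at the bottom so thoracic rows dominate; the running
sum converts velocity to displacement. If no feature is trackable the
extractor falls back to the vertical centroid of gradient energy, and only
if that also fails does it raise `no-motion-signal`. For the controlled
synthetic videos the reference experiments run the tracker single-level
with two iterations: frame-to-frame displacement there is far below one
pixel, the regime where a single linearized solve is already exact, and the
pyramid would only add cost.

Frames are mildly Gaussian-smoothed (sigma 2 px) before differentiation
inside the tracker: finite-difference gradients underestimate slopes for
textures with near-Nyquist content, which makes the least-squares flow
solve overshoot (we measured a 1.3x gain bias on aliased textures, and a
0.99 gain after smoothing on analytically shifted band-limited images).

Conditioning follows a fixed order: least-squares detrend, zero-phase
fourth-order Butterworth bandpass (0.1–0.6 Hz), three-sigma normalization
`(x − mean) / (3 sd)` with the population SD. The bandpass is applied
forward and backward, squaring the magnitude response and cancelling the
phase; because narrow-band IIR transients are long relative to a 60-s
recording, the input is first extended by odd reflection over roughly three
periods of the low band edge and trimmed afterwards. The in-band and
stop-band behavior is checked against the closed-form squared Butterworth
magnitude (`butterworth_bandpass_gain`).

Classical fusion computes `0.8 * chest + 0.2 * face` from the conditioned
chest-motion and face-rPPG signals. The chest weight reflects its stronger
mechanical coupling; the face term contributes independent information that
averages down chest disturbances. `sweep_fusion_weights()` re-runs the
whole grid. The spectral SNR used to compare channels is not uniquely
defined in the literature; here it is the periodogram power within ±0.05 Hz
of the reference rate over the remaining power in [0.05, 1.0] Hz, in dB.

For the learned path the four conditioned channels are scaled by their
region weights (chest channels ×0.8, face ×0.2) before windowing — the
region weighting is genuinely ambiguous between the classical fusion
equation and the network input specification, so both placements are
provided: an explicit fused single channel for the classical estimator, and
channel scaling ahead of the embedding for the network.

Windows are `win_len = 256` frames (within the 200–300 design range) with
stride 32 (87.5% overlap, within 80–90%) for pipeline use; the training
studies use stride 128 to keep epoch sizes proportionate to the information
actually present in heavily overlapping windows.

## The network

The architecture maps a T×4 window to a T×1 waveform with sequence length
preserved at every stage:

1. per-timestep affine embedding of the 4 channels into `d_model` features;
2. three 1-D convolution blocks with kernels 7, 5, 3 (same-length,
   centered zero padding), each conv → ReLU → batch normalization →
   dropout; channel width stays `d_model` throughout so the
   (batch, time, features) contract holds at every stage;
3. multi-head self-attention (8 heads at the default width, key width
   `d_model / n_heads`), scaled by `1/sqrt(d_k)`, with output projection,
   dropout, residual connection and layer normalization;
4. a two-layer bidirectional LSTM whose per-direction hidden width is
   `d_model / 2`, so the concatenated forward/backward states restore
   `d_model`; forget-gate biases initialize at +1;
5. a three-stage convolutional decoder `d_model → 64 → 32 → 1` with kernels
   5, 3, 1, mirroring the encoder's decreasing-kernel design (the final
   1-wide stage is the terminal 1×1 convolution).

Choices the architecture description leaves open, resolved here: the
convolution stack precedes the attention block; the only residual
connection is the one around attention; batch-norm evaluation uses frozen
running statistics; the decoder kernel sizes (only widths are prescribed)
decrease 5/3/1. The training loss is mean squared error between predicted
and reference waveforms per window — the simplest loss consistent with
waveform regression; the reference is the belt trace resampled to the
camera rate, bandpassed and three-sigma normalized, so both sides live on
the same scale.

Training uses AdamW (learning rate 0.001, decoupled weight decay 1e-4),
batch size 32, dropout 0.2, and a reduce-on-plateau schedule (factor 0.5,
patience 5 epochs, monitored on validation loss — the factor and patience
are unprinted conventions). The best-validation parameters are returned.
Everything is seeded: initialization, shuffling and dropout masks derive
from one seed, and two runs with the same seed produce bit-identical loss
histories. Subject-level k-fold splitting (`subject_kfold_split`, k = 5,
70/10/20 train/validation/test by subject) guarantees no subject crosses
the train/test boundary; the group protocol reuses it.

The whole network — embedding, convolutions, batch/layer normalization,
attention, BiLSTM, decoder, and AdamW — is implemented directly in R
matrix code with hand-derived backpropagation, verified against central
finite differences across every parameter group in the test suite.

Two width configurations are used. The full default (`model_config()`,
d_model 128, 8 heads) is the reference architecture and is exercised
by the shape and contract tests. The synthetic training studies use
`experiment_model_config()` (d_model 16, 2 heads, identical structure):
mapping four already-conditioned channels to a waveform is a far simpler
problem than raw video analysis, the narrow model recovers RR on held-out
subjects equally well, and it trains an order of magnitude faster on one
CPU.

## Spectral rate estimation

A predicted waveform is detrended and bandpassed once more (network output
can carry baseline drift), then analyzed with Welch's method: 512-sample
segments (about 17 s at 30 fps), 50% overlap, Hamming taper, segment means
removed, periodograms averaged, zero-padded to nfft = 8192 so the frequency
grid step is about 0.0037 Hz ≈ 0.22 BPM — the worst-case half-bin
quantization error is below 0.25 BPM. Signals shorter than one segment fall
back to a single full-length segment with a warning. The rate is the
argmax of the PSD restricted to 0.1–0.6 Hz (ties break toward the lower
frequency, documented and tested) times 60. The classical path skips the
second filtering pass — its channels are already bandpassed, and filtering
twice would attenuate band-edge rates (6 BPM sits exactly on the low edge)
enough to let the second harmonic win.

One RR is reported per recording, from the overlap-averaged full waveform;
per-window rates are available for diagnostics.

## Synchronization and evaluation

The camera and belt are independent acquisition systems, so alignment uses
normalized cross-correlation after resampling the belt to the camera rate
(linear interpolation) and bandpassing both. The lag maximizing the
correlation within ±10 s is applied to the camera signal; positive lag
means the camera stream leads. Ties break toward the smaller absolute lag,
and a peak below 0.2 triggers a `sync-unreliable` warning with zero lag
applied — near-periodic breathing makes ±one-period aliases genuinely
ambiguous, and only the natural rate variability of real (or realistically
simulated) breathing disambiguates them.

Agreement statistics follow the standard conventions: MAE and RMSE over
per-recording rates; Bland–Altman differences defined as predicted −
reference with limits of agreement mean ± 1.96 × sample (n−1) SD; Pearson
product-moment correlation. `run_group_protocol()` evaluates tone groups
within-group (subject-level splits) and across (train on one tone, test on
the other), never mixing a subject between train and test.

## What the synthetic generator emulates — and what it does not

Every recording is a pure function of a `synthetic_scene` and its seed.
The generator emulates, with one mechanism each:

* **Breathing waveform**: `sin(phi) + 0.3 sin(2 phi)`; the second harmonic
  stands in for non-sinusoidal breath morphology (its amplitude is a proxy,
  not a calibrated model). With `rr_var_bpm > 0` the instantaneous rate is
  frequency-modulated by two slow incommensurate oscillations with seeded
  phases; the phase is their closed-form integral, so camera and belt
  samplings are consistent at any clock offset. Scene primitives default to
  stationary breathing (`rr_var_bpm = 0`), which keeps the spectral-fidelity
  invariants exact; cohorts (`make_cohort`) default to 0.75 BPM of
  variability, a realistic resting value, and this variability — not sensor
  noise — sets the error floor of any spectral-peak estimator on 60-s
  recordings.
* **Skin tones**: the light preset has mean reflectance ≈ 200 with
  respiratory green-channel amplitude 2.0; the dark preset ≈ 120 with 0.8.
  These are artifact constants chosen so the tone-ordering phenomena are
  reproducible at desk scale, not measured physiology. Chest rPPG carries
  0.6× the facial respiratory amplitude (chest skin has the weaker
  perfusion signal); chest *motion* remains the strongest channel.
* **Chest mechanics**: the torso's upper edge and its texture translate
  rigidly with breathing (peak 3 px by default), with sub-pixel edge
  coverage so motion is smooth. Texture contrast scales with reflectance.
* **Disturbances**, all scaled by the scene's `noise_sd` so a noiseless
  scene is exactly clean, and structured the way one acquisition would
  produce them — shared physical causes are common across channels:
  white per-pixel sensor noise; multiplicative illumination drift;
  postural sway (one body: a random-walk drift plus a quasi-periodic
  rocking oscillation at a random 0.08–0.45 Hz frequency, common to both
  motion channels — the rocking is the disturbance a spectral-peak
  estimator genuinely cannot distinguish from breathing without consulting
  the rPPG channels); colored photometric wander (one light source, common
  to both rPPG channels) landing partly inside the respiratory band; and
  feature-tracking drift (one frame stream: a common plus a per-tracker
  random-walk component) whose rate grows with the cube of inverse
  reflectance. The cubic exponent is an emulation constant calibrated so
  the dark-to-light MAE ratio of the fused classical estimate is roughly
  two — the degradation magnitude reported for darker skin tones in
  camera-based RR studies — rather than a physical law.
* **Belt reference**: sampled at 10 Hz with an injectable clock offset that
  shifts the sample stream itself, so cross-correlation genuinely has to
  recover it.

This disturbance structure makes the skin-tone effect information-
theoretic rather than cosmetic: when the motion channels contain a
rhythmic competitor, only the rPPG channels can disambiguate breathing
from rocking, and their usefulness is exactly what melanin attenuation
removes. Tone-group comparisons consequently use **matched twin cohorts**:
the light and dark cohorts share every physiological and disturbance
realization and differ only in the tone profile, so comparisons are paired
and the tone effect is isolated from between-subject variability. With
unpaired cohorts the tone effect (tenths of a BPM) is buried under the
rate-variability error floor at any desk-scale cohort size; the paired
design exposes it reliably.

Rendered frames are 8-bit PNGs; the static skin speckle acts as spatial
dither, so sub-integer modulation (the dark preset's 0.8) survives
averaging over a few thousand mask pixels. Controlled numerical
experiments use the unquantized in-memory frame source.

Not emulated: real facial appearance and pose variation, clothing,
occlusion, camera compression, ambient light spectra, cardiorespiratory
coupling beyond a fixed cardiac tone. Consequently, passing the synthetic
studies demonstrates that the algorithms are implemented correctly and that
the pipeline's behavior under controlled signal-quality differences matches
the expected qualitative structure (tone orderings, fusion benefit, SNR
ranking); it does not certify accuracy on real subjects.

## Reference experiment designs

Problem sizes are the package's choices for reproducible single-CPU
studies:

* `classical_recovery_experiment()`: 10 rendered noiseless 60-s videos
  (rates 6–30 BPM × both tones) through the full video pipeline, with the
  tracker in its single-level/60-corner configuration (sub-pixel rigid
  motion needs neither a pyramid nor dense features).
* `recovery_study()`: 40 training and 10 held-out synthetic subjects
  (60 s each, mixed tones, natural rate variability), reduced-width model,
  30 epochs, batch 32, windows of 256 at stride 128.
* `group_study()`: 24 matched twin subjects per tone group, within-group
  60/40 train/test splits plus both cross-tone scenarios, 20 epochs. Both
  arms share the subject split and the training seeds, and every scenario
  is averaged over two paired training replicates, so the comparison
  isolates the tone effect from subject sampling and training
  stochasticity. At this design the cross-tone ordering (train-on-light
  degrades more on dark than vice versa) reproduces consistently; the
  within-group dark excess is a small effect (~0.01–0.02 BPM over a
  ~0.2 BPM rate-variability floor) that can tie at unlucky seeds.
* `snr_study()`, `sync_study()`: 20-recording SNR comparison and a 0.5-s
  belt-offset recovery. The SNR claim is an aggregate (cohort-mean)
  ordering: individual recordings with large rocking draws can invert it.
* The fusion sweep (`sweep_fusion_weights`) runs on a 30-subject
  mixed-tone cohort at the default noise level. An honest caveat: under
  this generator's disturbance structure the sweep does *not* reproduce a
  U-shaped error curve with its minimum at the chest-dominant weighting.
  The rhythmic-sway competitor lives only in the motion channels, so extra
  facial weight helps almost everywhere in the printed 0.5–1.0 grid — even
  a degraded dark-tone rPPG channel still disambiguates rocking from
  breathing. What does reproduce robustly is the complementary-information
  direction that motivates weighted fusion: chest-only estimation is
  clearly worse than fused weighting whenever body motion is substantial,
  which the test suite asserts. A U-shape would require motion artifacts
  to contaminate the rPPG channels as well (as they do in real video
  through region-tracking error); that coupling is deliberately absent
  here because the rPPG channels serve as the tone-sensitive
  disambiguators in the fairness experiments. The 0.8/0.2 default is
  retained as the method's reference configuration, not as the optimum of
  these synthetics.

## Known limitations

* The Lucas–Kanade tracker assumes approximately rigid, small-per-frame
  motion inside the chest ROI; large abrupt movements are outside its
  regime (the centroid fallback is cruder still).
* The skin-blob face detector is a geometric heuristic, not a trained
  detector; on real footage a proper cascade or CNN detector should be
  plugged into the `detector` argument.
* Spectral-peak RR estimation reports one rate per recording and cannot
  track within-recording rate changes; the FM variability of the synthetic
  cohorts makes this an explicit, quantified error floor rather than a
  hidden one.
* Batch normalization statistics are those of the last training batches
  (standard running-average convention); very small training sets make
  evaluation-mode statistics noisy.
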