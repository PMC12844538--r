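---
title: "Multimodal music-emotion regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal music-emotion regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

museeg predicts a listener's continuous emotional response to music —
valence (positivity) and arousal (intensity) on the 9-point circumplex
rating scale — from two modalities recorded together: the audio itself and
32-channel EEG in the layout of the DEAP preprocessed release (32 subjects
× 40 one-minute trials, EEG at 128 Hz). This vignette documents the models,
the tunable parameters, the synthetic data generator the package is tested
on, and the numerical and design choices a maintainer would want to know
about.

## Feature extraction

### Audio timbre descriptors

Audio is mixed to mono and cut into 1-second windows with 50% overlap. A
window is emitted if and only if its end lies *strictly* before the track
duration; this is the unique simple rule that yields 118 windows for a 60 s
track (the inclusive rule would give 119). Each window is Hann-tapered —
the taper is our choice, it reduces leakage and matches common practice —
and transformed; from the magnitude spectrum `m_k` on bins `f_k` we form
the L1-normalized distribution `p_k = m_k / sum(m)` and compute five
spectral-shape (timbre) descriptors:

* **centroid** `C = sum(f_k p_k)` (Hz) — spectral center of mass;
* **spread** `sqrt(sum((f_k - C)^2 p_k))` (Hz) — width around the centroid;
* **skewness** `sum((f_k - C)^3 p_k) / spread^3` — spectral asymmetry;
* **entropy** `-sum(p_k log p_k) / log K` — flatness in `[0, 1]`;
* **flux** — Euclidean distance between consecutive L1-normalized spectra
  (0 for the first window).

All five are invariant to overall gain. Zero spectra (silence) map to zeros
rather than NaN; skewness is 0 by convention when the spread is 0. The
transform length equals the window length and no zero-padding is applied;
since no reference implementation of the descriptors is bit-defined, exact
numeric parity with any particular audio toolkit is not claimed — the
formulas above are the contract, and tests enforce them against brute-force
oracles at 1e-9.

### EEG band-power features

EEG trials (32 × 7680 samples at 128 Hz) are band-limited to 0.5–45 Hz with
cascaded 4th-order Butterworth high- and low-pass halves, each applied
forward-backward (zero phase). The cascade, rather than a single 8-pole
band-pass prototype, is a numerical choice: at a normalized low edge of
0.0078 the band-pass transfer-function form is poorly conditioned, while
the cascade measures a gain of 1.000 at 10 Hz and effectively 0 at 60 Hz.

Power spectral density is estimated per channel by Welch averaging:
Hann-tapered 2 s (256-sample) segments, 50% overlap, one-sided density
scaling (the PSD integral approximates the variance; tested to 20% on white
noise). Welch variance reduction keeps band peaks stable; a full-length
periodogram is available via `compute_psd(method = "periodogram")`. PSD is
computed once per trial; a per-window mode was considered and rejected as
the default because the minute-scale trials are stationary by construction
and per-trial spectra keep the feature count at the documented 320.

For each channel and each canonical band — delta 0.5–4, theta 4–8, alpha
8–13, beta 13–30, low gamma 30–45 Hz — the features are the grid frequency
with the highest PSD and that PSD value (dominant oscillatory activity):
32 × 5 × 2 = 320 features. Ties break toward the lower frequency for
determinism. Peak powers enter the model as log10 values since line powers
span decades.

## The fusion model

Three branches produce length-2 outputs that are **summed** into
(valence, arousal); fusion is additive, so each branch learns a residual
correction to the others.

* **MLP branch** (tabular features): dense 910→1000, ELU, dense 1000→1000,
  ELU, dense 1000→2. The input is the 590 flattened timbre features
  (118 windows × 5) plus the 320 EEG band-peak features. Whether EEG
  features also feed the MLP is switchable
  (`use_eeg_features_in_mlp`, default `TRUE`); the audio-only ablation
  model always uses the 590 timbre features alone. A published description
  of this architecture family prints an input width of 1278, which cannot
  be reconciled with any stated feature composition (590 + 320 = 910); the
  package therefore defaults to the actual composed width and accepts an
  explicit `mlp_input_dim` override.
* **Audio CNN branch**: the raw waveform resampled to
  `audio_branch_rate` (default 64 Hz; see below).
* **EEG CNN branch**: the 32-channel log-PSD matrix treated as 32 parallel
  sequences over the frequency axis.

Both CNN branches share one compact architecture in three blocks:

1. 1-D convolution, 8 filters, kernel 9; depthwise convolution to 16
   channels (depth multiplier 2 — the only realizable reading of "16
   depthwise filters after an 8-channel layer"), kernel 32; ELU; average
   pooling by 4; dropout 0.5.
2. depthwise convolution, kernel 26; pointwise (kernel-1) convolution
   mapping 16→16 channels (the count is unstated upstream; we preserve the
   block width); ELU.
3. flatten; dense to 200; dense to 2 (no activation between the two head
   layers).

All convolutions use "same" padding so short inputs survive the large
kernels; inputs must still be at least `pool_factor * 26 = 104` samples
long, validated at build time. The MLP nonlinearity is ELU, matching the
CNN blocks for uniformity. Output clipping to `[1, 9]` exists but is off by
default: metrics are computed on raw sums, consistent with unconstrained
regression.

**Why 64 Hz for the waveform branch?** The branch input representation is
deliberately coarse. At a musically realistic rate (say 1 kHz) the
first-block activations would be 15 000 × 16 and the flatten-to-dense layer
alone would hold ~48 M weights — far beyond desk scale, and pointless here:
fine spectral detail already reaches the model through the timbre features,
so the waveform branch contributes envelope-scale temporal structure. At
64 Hz the whole three-branch model has ≈ 5 M parameters and a single-CPU
training epoch at the study size takes about two seconds. The rate is a
config field, not a constant.

The implementation is a small reverse-mode layer framework written for this
package (R with compiled grouped-convolution kernels); no deep-learning
runtime is required. All layer gradients are verified against central
finite differences at 1e-5 relative tolerance, and the conv primitives are
exercised by shape, bias-propagation and parameter-count contracts.

## Training and evaluation

Trials are split 8:1:1 (train/validation/test) by seeded permutation, with
`floor(n/10)` (at least 1) in each held-out part and the remainder in
train. Standardization (features per column, waveform globally, PSD per
frequency–channel cell) is fit on the training rows only. The loss is mean
absolute error; the optimizer is Adam at learning rate 2e-3 with batch size
16. Training stops when validation MAE has not improved for `patience`
(default 20) epochs, up to `max_epochs` (default 250), and the weights of
the best validation epoch are returned. None of these values is prescribed
by the underlying study; they were chosen during development for stable
single-CPU convergence at the package's study sizes (at hundred-example
scale, smaller batches give Adam enough steps per epoch to find sparse
informative directions — e.g. a handful of band-power columns among 910
features — before early stopping triggers) and are arguments of
`train_fusion()`. All randomness — split, initialization, dropout, batch
order — derives from the run seed, and repeated runs are bit-identical.

Metrics are the standard forms: MAE `= (1/n) Σ|y − x|`, MAPE
`= (100/n) Σ|(y − x)/y|`, `R² = 1 − Σ(y − x)²/Σ(y − ȳ)²`, reported pooled
over the concatenation of valence and arousal as well as per target. MAPE
is well defined here because ratings live in `[1, 9]`; a zero truth raises
a structured error rather than returning infinity.

The EEG-off **ablation** (`run_ablation()`) trains the full model and the
audio-only control on identical splits and seeds: the control keeps the MLP
(timbre features only) and the waveform CNN and has no EEG-consuming
parameter, so its forward pass is bit-identical under arbitrary EEG input —
a property the tests assert directly.

**Channel attribution** (`attribute_channels()`) scores each electrode of
the trained full model by mean `|gradient × input|` over the evaluation
set, summed over both output targets and over *all* EEG-derived inputs of
that channel — its PSD column in the CNN branch and its ten band-peak
features in the MLP. Importance genuinely flows through both paths, so
restricting attribution to one of them would under-count. An occlusion
variant (replace one channel's inputs with the training mean, i.e. zero in
standardized space, and measure the increase in test MAE, floored at 0) is
available as a cross-check; both agree on the planted channels in the
acceptance suite.

## The synthetic data generator

`generate_dataset()` emulates the DEAP layout — 32 subjects × 40 trials,
60 s, 32 EEG channels at 128 Hz, paired audio, ratings in `[1, 9]` — with a
known generative link between signal properties and labels, so the whole
pipeline is testable without any gated download:

* latent valence and arousal are uniform on `[1, 9]` (uniform rather than
  DEAP's empirical rating distribution: uniformity maximizes
  identifiability for recovery tests); ratings are the latents plus
  Gaussian rating noise (`noise_sd`, default 0.5 rating units — a
  realistic self-report jitter well below the rating range) clipped to
  `[1, 9]`;
* audio is a stack of 8 harmonics of 220 Hz whose amplitudes follow
  `h^(-gamma)` with `gamma` decreasing in valence, normalized to constant
  total amplitude, plus a low white-noise floor. The spectral centroid
  therefore rises monotonically with valence. (The constant-mass
  normalization matters: with a fixed noise floor and growing tone mass the
  centroid of the *mixture* would fall with valence.)
* EEG is one sinusoid per band per channel (random frequency within the
  band interior, random phase) over `1/f` background noise (power exponent
  1, amplitudes scaled so band peaks stand clear of the noise floor under
  the default PSD settings). On the designated `signal_channels` (default
  Fp1, Fp2, P3, P4) the alpha amplitude scales as `exp(-0.45 g)` and beta
  as `exp(+0.45 g)` with `g` the normalized arousal, making the log
  beta/alpha power ratio linear in arousal; all other channels are
  label-independent. Valence is planted predominantly in audio and arousal
  exclusively in EEG, so removing the EEG modality must cost arousal
  accuracy — the ablation has a guaranteed direction.

Waveforms and EEG matrices are synthesized on demand from per-trial seeds
(`trial_audio()`, `trial_eeg()`): the full 1280-trial dataset is a list of
light records rather than 13 GB of arrays, and the same master seed always
reproduces identical signals, byte for byte. The DEAP-format fixture writer
adds the 3 s baseline prefix, 8 white-noise peripheral channels and
(dominance, liking) placeholder columns purely for format fidelity.

What the generator does *not* emulate: music structure beyond spectral
statistics (no onsets, rhythm, or harmony changes), ERP morphology,
eye-blink or muscle artifacts (inputs are assumed artifact-cleaned, as in
the DEAP preprocessed release), inter-subject variability, and any
nonlinear or cross-modal label dependence. Passing tests on this generator
demonstrates that the pipeline recovers planted monotone links under
realistic noise floors — not that the model reaches any particular accuracy
on real recordings.

## Study sizes used by the test and acceptance runs

The package's own experiments run at deliberately reduced scale, chosen
once as a realistic desk-scale study: the end-to-end learning and
attribution checks use 8 subjects × 20 trials (160 trials; 128/16/16
split) with the arousal signal planted in Fp1/Fp2 only, so one trained
model serves both the ablation contrast and the attribution-recovery
check. Feature preparation for those 160 trials takes a few minutes and
each training run a few more on one CPU. The dataset-shape checks use the
full 1280-trial default configuration, which is cheap because signals are
lazily synthesized.

## Known limitations

* The DEAP reader consumes the release's *layout* serialized as RDS; the
  original Python-pickle files must be converted externally once.
* The waveform branch sees a 64 Hz signal; claims about what raw-audio
  CNNs learn at full audio bandwidth are out of scope.
* Welch parameters (2 s segments, 50% overlap) are fixed defaults; very
  short trials (< 2 s) are rejected rather than silently re-windowed.
* Attribution is reported at the channel level only; no within-band or
  time-resolved attribution is attempted.
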