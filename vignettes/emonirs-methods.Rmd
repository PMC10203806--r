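---
title: "Methods: prosody attenuation and simulation-validated fNIRS analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prosody attenuation and simulation-validated fNIRS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emonirs)
```

This vignette is the package's account of its own methods: the models it
implements, the assumptions behind them, the parameters that matter and why
their defaults are what they are, what the synthetic-data generators do and
do not emulate, and the numerical choices made where several were possible.

## The scientific problem

Listeners recognise vocal emotion mainly from three prosodic features:
fundamental frequency (F0), intensity, and speech rate. Attenuating the
variation of a feature — flattening its trajectory onto a constant corpus
mean — renders that cue uninformative while leaving the rest of the signal
intact. Pairing such manipulated speech with a four-alternative
forced-choice (4-AFC) recognition task and block-design fNIRS recordings
lets one ask (a) how strongly behaviour depends on each cue, and (b)
whether cortical haemodynamic responses, particularly in right superior
temporal gyrus (STG), reflect the presence or absence of rich F0 cues.

Because human recordings are not distributable, every stage here is paired
with a seeded generator that produces data *with known ground truth*, so
the full analysis chain is validated by parameter recovery rather than by
reproduction of the original human estimates.

## Stimulus surrogates and prosody manipulation

`synth_sentence()` builds six-syllable utterance surrogates: harmonic
complexes (8 harmonics, −6 dB/octave roll-off) that follow an F0 contour by
phase accumulation, shaped by raised-cosine ramps (15 ms) and per-syllable
gains, with silent inter-syllable gaps. These surrogates carry exactly the
three features under study and nothing else — no formants, no segmental
content — which is what makes oracle-based testing of the manipulations
possible.

The three attenuation stages, composed in the fixed order
F0 → rate → intensity:

* **F0 flattening** (`attenuate_f0`) uses TD-PSOLA: pitch marks are placed
  along the tracked contour, two-period Hann grains are extracted at the
  marks and re-placed at the constant target period (217 Hz by default,
  the rounded corpus grand mean). Any analysis/resynthesis method meeting
  the post-conditions (tracked F0 within ±3 Hz of target, duration within
  1%, unvoiced spans untouched) would be conformant; PSOLA was chosen
  because it is exact on quasi-periodic surrogates and fully in-package.
* **Rate scaling** (`attenuate_rate`) is uniform, sentence-level WSOLA:
  the output length is fixed to `n_syllables / target` (4.82 syl/s
  default) and segments are aligned by cross-correlation so pitch is
  preserved. Scale factors outside [0.25, 4] are rejected as a quality
  guard.
* **Intensity equalisation** (`attenuate_intensity`) drives the short-time
  RMS envelope (50 ms frames) onto the target level (−11.19 dB relative to
  the bank's maximum RMS) inside speech; samples below a −40 dB silence
  floor keep unit gain. Gains are estimated on the *speech interior* —
  at least one frame length inside a speech/silence boundary, where the
  envelope estimate is unbiased — and extended across onset/offset ramps,
  with a second correction pass. A frame straddling silence cannot
  mathematically reach the frame-RMS target, so "speech-active" frames in
  the companion measurement (`frame_levels`) are those lying fully inside
  speech; their *mean* level lands within ~0.1 dB of target, while
  individual frames carry ±0.4 dB ripple from unsynchronised pitch periods
  within the 50 ms window. An utterance-global variant (`global = TRUE`)
  is available because the corpus description does not fix frame-wise
  versus global equalisation; frame-wise is the default as the stricter
  reading.

**The stimulus bank** (`make_stimulus_bank`) draws per-sentence deviations
from per-emotion norms (mean F0 241.47/243.31/215.97/167.04 Hz for
angry/happy/sad/unemotional, with the tabulated SDs, levels, and rates)
and re-centres the deviations so each emotion's realised mean matches its
norm — the bank is *calibrated*, as a recorded corpus whose statistics are
reported post-hoc effectively is. F0 contours are sinusoidal modulations
(depth 12%, 2–4 cycles per sentence) normalised on the tracker's own
frame grid, because the reported statistics are themselves tracker
outputs. Sentence levels are expressed relative to the realised bank
maximum RMS, so the absolute per-emotion levels shift by the sample
maximum of the drawn levels (≲0.5 dB); relative level structure and the
dB-re-max semantics are preserved exactly.

## Trial design

`make_afc_schedule()` gives practice trials followed by one presentation
of every emotion × condition × sentence stimulus in seeded random order
(100 test trials at full size; 40 in the two-condition pre/post variant).
`make_block_schedule()` gives 4 familiarisation trials, then a random
interleaving of 20 repetitions of each of 5 conditions and 2 repetitions
of each of 5 attention stimuli (114 trials), ISIs uniform on 13–23 s.
Uniform ISIs and unconstrained attention-trial placement are design
choices; only the range and counts are fixed by the protocol.

## Forward simulation of fNIRS recordings

`simulate_concentrations()` builds per-channel HbO/HbR time courses in µM
at the instrument rate (2.6 Hz):

* long channels: the sum over conditions of `beta × (3-s boxcar ⊗ HRF)`
  for their ROI, plus systemic components;
* short channels (8 mm): systemic components only — shared latent
  sinusoids (Mayer ~0.1 Hz, respiration ~0.25 Hz, cardiac ~1.1 Hz) with
  channel-specific weights (SD 0.3 around 1, the "location-dependent
  heterogeneity"), random-walk drift, and white noise.

Default amplitudes (µM, HbO scale): Mayer 0.5, respiration 0.2, cardiac
0.3, white noise SD 0.3, drift SD 0.01/sample — systemic power of the same
order as the 1 µM response amplitude, which is the regime short-channel
regression exists for. HbR carries −1/3 of the neural amplitude (typical
physiology; configurable) and 0.5× the systemic scale. The cardiac
component aliases at 2.6 Hz sampling and is kept deliberately as a stress
on the pipeline. `concentrations_to_raw()` then applies the inverse
modified Beer–Lambert law, `I = I0 exp(−(ε_HbO C_HbO + ε_HbR C_HbR) d ppf)`,
with base-10 extinction coefficients from the standard compiled
haemoglobin spectra converted to natural-log µM·cm units.

What the generator does *not* emulate: motion artifacts, photon-transport
head geometry, heavy-tailed noise, inter-channel neural heterogeneity
within an ROI, and serial correlation beyond what the systemic components
induce. Passing recovery tests therefore demonstrates correctness of the
estimation chain under this model, not robustness to artifacts the model
excludes.

## First-level analysis

`fit_first_level()` follows the standard chain: polyphase resampling
2.6 → 0.6 Hz (ratio 3/13), optical density from absolute intensities
(natural log; consistent with the extinction units), modified Beer–Lambert
with partial pathlength factor 0.1 (DPF 6 / partial-volume correction 60),
long-channel selection by inclusive 20–40 mm distance bounds, and per
channel × chromophore an AR(1)-prewhitened GLM.

Numerical choices worth recording:

* **Regressors.** Condition columns are the *exact continuous*
  boxcar ⊗ HRF response (fine-grid cumulative HRF integral, interpolated
  at sample times, unit single-block peak so betas are µM). At 0.6 Hz a
  3-s boxcar is one or two samples; integer stick discretisation makes
  regressor amplitude depend on onset phase (errors up to ~40%), which the
  continuous construction eliminates. Simulator and analysis share the
  constructor, so recovery error isolates estimation.
* **Resampling.** A windowed-sinc polyphase resampler (Hamming,
  half-order 10, reflection padding, group-delay compensation) is
  implemented in-package; it preserves a 0.05 Hz sinusoid's amplitude to
  0.1%.
* **HRF.** Difference of gammas with response peak 6 s, undershoot peak
  16 s, undershoot ratio 1/6, unit peak.
* **Drift.** Discrete cosine basis up to 0.01 Hz: `floor(2·T·f_c)`
  columns plus a constant; the basis is a choice, only the cut-off is
  fixed by the protocol.
* **Short-channel nuisance.** All principal components of the 8 centred
  short-channel series, per chromophore, jointly across ROIs, each scaled
  to unit variance; degenerate components are dropped with a message.
* **AR(1).** Per-channel iterative prewhitening: OLS, lag-1 residual
  autocorrelation, exact AR(1) transform (first row scaled by
  √(1−ρ²)), refit; stop at |Δρ| < 10⁻³ or 10 iterations. `rho = 0`
  reproduces OLS exactly; a perfect fit returns ρ = 0 by a relative
  residual-scale guard.
* **ROI pooling.** Inverse-SE weights (w = 1/se) with propagated error
  √(Σw²se²)/Σw. The protocol wording admits 1/se or 1/se²; 1/se is the
  default, 1/se² available via `weighting = "inv_var"`.

`epoch_average()` provides the grand-average waveforms (−5 to +30 s
window, pre-onset baseline, t-based 95% band across epochs) for visual
inspection.

## Second-level and behavioural statistics

`fit_cellmeans_model()` fits, per chromophore, REML linear mixed models
with suppressed intercept (`0 + ROI:Condition`, 30 cells at full size),
participant random intercepts, and condition random coefficients; a
singular maximal fit falls back to the intercept-only structure with a
message (mirroring the forward-stepwise simplification such analyses
use). Cell tests against zero and planned contrasts use the normal
approximation for mixed-model linear combinations — at N ≈ 660 rows the
difference from Satterthwaite degrees of freedom is negligible; this is a
documented approximation, not an equivalence claim. Contrast families are
FDR-corrected by an in-package Benjamini–Hochberg step-up
(cross-checked against `p.adjust` in the tests). `cooks_exclude()`
computes Cook's distance from the fixed-effects regression via the hat
matrix and excludes rows above 4/N (the threshold is a convention; the
protocol names none).

Behaviour: `simulate_behavior()` draws 4-AFC responses from a softmax
cue-weighting model — per-emotion correct-response baselines, per-cue
log-odds penalties when a cue is attenuated, an "unemotional" bias added
when F0 is flat (which lands on the *correct* response for unemotional
speech, reproducing its immunity to F0 flattening), and participant
ability intercepts. Defaults were calibrated once to the published
accuracy structure (overall ≈ 0.65; a small drop when intensity+rate are
attenuated; a large drop when F0 is attenuated). `fit_accuracy_glmm()`
fits logit GLMMs with sliding-difference or treatment codings
(`sliding_diff_coding()` has the closed form entry(i,j) = −(k−j)/k for
i ≤ j, else j/k, so that the difference matrix times the coding is the
identity), uncorrelated random intercepts/slopes, an SD < 0.01 drop rule
and likelihood-ratio retention tests. `nakagawa_r2()` computes
marginal/conditional R² from the fitted variance components (π²/3
residual variance on the logit scale).

`brain_behavior_model()` regresses ROI amplitudes on each participant's
pre-session accuracy (`0 + roi + roi:accuracy`, participant random
intercept) per chromophore — the accuracy slope per ROI is the quantity
of interest. `hbo_hbr_difference()` reports |θ_HbO − θ_HbR| with pairs
classed by sign opposition; classification by within-epoch time-course
correlation is a plausible alternative reading, and sign opposition is
the default without any claim about which was originally intended.

## Validation sizes and what the tests show

The recovery suite simulates 22 participants × 5 conditions × 6 ROIs per
replicate and 100 seeded replicates, using a compact montage (one long +
one short channel per ROI) and 8 block repetitions per condition: bias
and CI calibration are invariant to channel count and session length,
which only scale the standard errors, so the desk-scale sizes test the
same properties as the full 60-channel, 20-repetition session. Measured
over this design, the recovered amplitudes are unbiased to well under 5%
and the first-level CIs hold 90–99% empirical coverage; including the
short-channel components never increases recovery RMSE while systemic
noise is present. Second-level coverage, FDR control on 1000 global-null
24-contrast families, Cook's distance against brute-force leave-one-out,
and R² against a known variance partition are each checked in
`tests/testthat/`.

## Known limitations

* The stimulus surrogates are harmonic complexes; voice quality, formants
  and segmental cues are out of scope, so manipulation quality on real
  speech is untested here.
* Per-frame intensity accuracy is limited to ~±0.4 dB by pitch-period
  ripple at the 50 ms frame; the speech-active mean is accurate to
  ~0.1 dB.
* The AR(1) model does not whiten the shared low-frequency systemic
  residual perfectly at short session lengths; first-level SEs are
  slightly conservative in the default noise regime (coverage sits near
  the top of the 90–99% band).
* Scalp-coupling-index screening, motion correction and channel-wise
  (non-pooled) group analysis are intentionally not implemented.
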