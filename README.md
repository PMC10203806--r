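# emonirs

Tools for studying how the brain responds to vocal emotion when the
prosodic cues that carry it are taken away, using functional near-infrared
spectroscopy (fNIRS). The package is aimed at auditory cognitive
neuroscientists who want a fully testable, simulation-backed version of the
complete experimental computation: stimulus manipulation, task design,
forward simulation of fNIRS recordings, first- and second-level statistics,
and the brain–behaviour link.

## What it computes

**Prosody-cue attenuation.** Emotional prosody rides on three acoustic
features: fundamental frequency (F0), intensity, and speech rate. The
package synthesizes six-syllable pseudo-sentence surrogates, measures their
prosodic profiles, and attenuates feature variation onto corpus grand-mean
targets — F0 flattened to a constant 217 Hz by pitch-synchronous
overlap-add (TD-PSOLA), short-time intensity equalised to −11.19 dB
relative to the stimulus bank's maximum RMS, and syllable rate scaled to
4.82 syl/s by waveform-similarity overlap-add (WSOLA). Compositions of
these define the five stimulus conditions (`natural`, `intensity+rate`,
`F0`, `intensity+F0`, `rate+F0`), applied in the fixed order
F0 → rate → intensity.

**Trial design.** 4-AFC emotion-recognition schedules (4 emotions × 5
conditions × 5 sentences = 100 test trials) and fNIRS block designs
(5 conditions × 20 repetitions + 10 attention trials + 4 familiarisation
trials = 114 trials, ISIs uniform on 13–23 s).

**Forward simulation.** Dual-wavelength (760/850 nm) raw intensities at
2.6 Hz from known condition amplitudes: long channels carry
HRF-convolved condition responses plus Mayer-wave (~0.1 Hz), respiratory
(~0.25 Hz) and cardiac (~1.1 Hz) oscillations, random-walk drift and white
noise; 8 mm short-separation channels carry only the non-neural part.
Intensities follow the inverse modified Beer–Lambert law, so the analysis
chain can be validated by parameter recovery.

**First-level GLM.** Resample 2.6 → 0.6 Hz (polyphase 3/13), optical
density, modified Beer–Lambert law with partial pathlength factor
0.1 (= DPF 6 / PVC 60), channel selection (20–40 mm), a design of 3-s
boxcars convolved with the canonical double-gamma HRF plus discrete-cosine
drift (≤ 0.01 Hz) and all short-channel principal components, an AR(1)
prewhitened GLM per channel and chromophore, and standard-error-weighted
pooling into six regions of interest (bilateral STG, IFG, MFG):

  θ_ROI = Σ wᵢβᵢ / Σ wᵢ,  wᵢ = 1/seᵢ.

**Second level.** Linear mixed cell-means models with suppressed intercept
(`0 + ROI:Condition`, participant random intercepts and condition
coefficients), Cook's-distance screening (D > 4/N), planned contrasts with
normal-approximation inference and Benjamini–Hochberg FDR, sliding
difference and treatment contrast codings, logistic GLMMs of 4-AFC
accuracy with the standard random-effect simplification loop, confusion
matrices, Nakagawa marginal/conditional R², the accuracy × ROI
brain–behaviour model, and the unsigned HbO–HbR difference metric.

## Worked example

```r
library(emonirs)

# a glide sentence, flattened to the 217 Hz target
glide <- synth_sentence(sentence_spec(f0_contour = function(t) 150 + 100 * t,
                                      syllable_durations = 0.2,
                                      gap_durations = 0.05))
flat <- attenuate_f0(glide, 217)
trk <- track_f0(flat)
mean(trk$f0[trk$voiced])
#> [1] 217.2433

# simulate one participant and recover the condition amplitudes
mont  <- make_montage()              # 60 long + 8 short channels
sched <- make_block_schedule(seed = 1)   # 114 trials
rec   <- simulate_recording(mont, sched, default_truth(), noise_config(),
                            seed = 1)
fl    <- fit_first_level(rec, participant = 1)
r <- fl$roi_estimates
head(r[r$roi == "RSTG" & r$chromophore == "HbO", ])
#>    participant  roi   condition chromophore   theta       se n_channels
#> 6            1 RSTG       angry         HbO 1.29728 0.006900         10
#> 12           1 RSTG     control         HbO 0.00224 0.007210         10
#> 18           1 RSTG       happy         HbO 1.29789 0.006979         10
#> 24           1 RSTG         sad         HbO 1.30595 0.006927         10
#> 30           1 RSTG unemotional         HbO 1.29910 0.006978         10
```

`theta` is the recovered HbO response amplitude in µM; the simulated truth
for right STG is 1.3 µM (`default_truth()`), so the estimate should sit
within a couple of standard errors of it. Stacking `roi_estimates` over
participants feeds `fit_cellmeans_model()`, `contrast_family()` and
`brain_behavior_model()` for the group-level questions: does speech beat
silence in STG, is the response right-lateralised, and does the amplitude
fall as recognition accuracy rises?

## Layout

- `R/` — implementation (stimuli, schedules, simulator, first level,
  group statistics, IO, end-to-end pipeline)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/emonirs-methods.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations
- `scripts/acceptance.R` — endpoint reproduction script
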