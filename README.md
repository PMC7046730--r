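# vasrf

Virtual auditory space (VAS) stimuli and spatial receptive-field analysis
for auditory neuroscience.

## The scientific problem

A sound's direction must be computed from three acoustic cues: interaural
time differences (ITDs), interaural level differences (ILDs), and the
direction-dependent spectral filtering by head and pinnae (spectral cues).
To dissect which cue drives which part of a neuron's spatial receptive
field (RF), one plays head-filter-synthesized stimuli through earphones and
*freezes* one cue at a time — zero ITD, zero average ILD, or a flat
spectrum — while the other cues vary naturally with direction. `vasrf`
implements that entire computational chain for users analyzing (or
simulating) midbrain recordings from small-headed mammals, where ITDs are
negligible (≲ 29 µs for a 1 cm head) and the interplay of spectral cues
and ILDs builds a topographic map of azimuth.

## What is inside

* **HRTF engine** — complementary Golay-code pairs and impulse-response
  reconstruction (`generate_golay_pair()`, `reconstruct_hrir()`); HRIR
  grid container and cue extraction (`compute_itd()`, `compute_ild()`,
  `mirror_hemifield()`).
* **Stimulus builder** — 100-ms tapered VAS noise bursts
  (`synthesize_vas()`), cue freezing (`freeze_itd()`, `freeze_ild()`,
  `freeze_spectrum()`, `make_monaural()`), the ±40 dB extended-ILD set,
  and binaural dynamic random chords (`generate_random_chord()`).
* **Synthetic data** — a parametric mouse-like head filter
  (`make_synthetic_hrtf()`) and overdispersed spiking populations with
  known RF ground truth (`make_population()`).
* **Response statistics** — PSTHs, 5–20 ms window counts, overdispersion
  φ = var/mean, quasi-Poisson significance tests, binomial errors for
  categorical fractions.
* **RF fitting** — maximum-quasi-likelihood Kent-distribution fits with
  BIC model selection against a flat rate
  (`fit_kent()`), the radius relation ρ = arccos(1 − 1/(2κ)), and
  χ²-weighted topographic-map regression with a ±19° systematic error
  (`fit_topographic_map()`).
* **Cue similarity** — cosine similarity indices with error propagation,
  normalized similarity (NSI) losses, reproducibility filtering, and
  ILD-tuning classification (flat / monotonic / peaked).
* **STRF analysis** — binaural spike-triggered averages with per-pixel
  Bonferroni-corrected binomial significance (960 pixels), binaural
  similarity indices, and population fraction maps.
* **Pipeline** — `run_pipeline(run_config(...))` executes every stage on
  a simulated dataset and writes seed-stamped JSON/CSV artifacts.

The Kent density used for RFs, normalized to 1 at the center γ₁, is

    f(x) = exp(−κ) · exp{ κ γ₁·x + β [(γ₂·x)² − (γ₃·x)²] }

with concentration κ (RF size), ellipticity β (fits restrict 4β < κ), and
an orthonormal axis triple γ₁, γ₂, γ₃. Count likelihoods are
quasi-Poisson: variance φ·mean, realized by a moment-matched negative
binomial (φ = 1 is exact Poisson).

## Worked example

Simulate a 30-neuron population on a synthetic head filter, fit every RF,
and recover the topographic map:

```r
library(vasrf)

grid <- make_synthetic_hrtf(synthetic_hrtf_spec())
pop  <- make_population(30, map_slope = 58, map_offset = 14,
                        jitter_sd = 19, overdispersion = 5, seed = 1)
res  <- map_recovery_analysis(pop, grid, n_trials = 30, seed = 2)
res$map
#> <map_fit> slope 53.1 +- 7.5 deg/mm, offset 19.6 +- 7.1 deg, chi2/dof 0.56, r 0.87 (n = 30)
```

The fitted slope (degrees of RF azimuth per mm of anteroposterior
position) recovers the configured 58°/mm within its error; χ²/dof near 1
says the statistical-plus-systematic error model is calibrated, and `r`
is the Pearson correlation between position and fitted azimuth. Freezing
cues then quantifies what built those RFs:

```r
cue <- cue_freezing_analysis(pop, grid,
         list(frozen_itd = freeze_itd(grid),
              frozen_spectrum = freeze_spectrum(grid)),
         n_trials = 20, seed = 3)
colMeans(cue[cue$reproducible, c("nsi_loss_frozen_itd", "nsi_loss_frozen_spectrum")])
#>      nsi_loss_frozen_itd nsi_loss_frozen_spectrum
#>               0.00706829               0.65173646
```

Freezing the (negligible) timing cue costs nothing; flattening the
spectrum destroys roughly two thirds of the reproducible RF structure,
most of it in frontal neurons.

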