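---
title: "Models and methods behind vasrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vasrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasrf)
```

# The problem

A sound's direction is not given to the brain directly; it must be computed
from three acoustic cues: the interaural time difference (ITD), the
interaural level difference (ILD), and the direction-dependent spectral
filtering of the head and pinnae (spectral cues). `vasrf` implements the
computational chain used to dissect the contributions of these cues to
auditory spatial receptive fields (RFs) in the midbrain of a small-headed
mammal: virtual auditory space (VAS) stimuli synthesized from head-related
impulse responses (HRIRs), selective *freezing* of individual cues,
quasi-Poisson response statistics, Kent-distribution RF fits, similarity
indices between cue conditions, and binaural spectro-temporal receptive
fields (STRFs) from dynamic random chords.

Because real silicon-probe recordings cannot ship with a package, a
first-class synthetic-data module generates both the head filter and the
neural population with *known* ground truth, so every downstream stage can
be validated end to end.

# Coordinate frames

Directional data live on the sphere, and two frames are used deliberately:

* **front-Z** (polar axis rostral) is the frame of HRIR measurement and
  stimulus presentation: a motorized polar stage naturally samples
  azimuth 0-180 degrees around the nose axis.
* **top-Z** (polar axis dorsal) is the frame of RF fitting: front-Z has an
  azimuth discontinuity across the frontal midline exactly where frontal
  RFs sit, and fitting in top-Z avoids it.

`convert_frame()` is an exact change of polar axis, and the Kent model is
defined on unit vectors, so fitted parameters do not depend on the frame;
only the reported angles do. Map analyses keep neurons with fitted
elevation below 30 degrees, where the two frames' azimuths are close.

# Cue extraction conventions

The HRIR grid (`hrir_grid()`) stores per-direction, per-ear impulse
responses at 500 kHz; analysis is restricted to the 5-80 kHz band that the
playback hardware the protocol assumes can reproduce.

* **ITD** is the difference of integer-sample argmax-of-|h| peak times,
  right minus left, in microseconds. No sub-sample interpolation is used:
  at 500 kHz the 2 microsecond resolution is far below the ~29 microsecond
  physiological maximum of a ~1 cm head (`d/c` with `d = 0.01` m,
  `c = 343` m/s). Ties break to the earliest sample.
* **ILD** per frequency is the right-minus-left dB magnitude spectrum;
  the broadband ILD averages the dB spectrum over band bins per ear before
  subtracting. Whether "average amplitude" should be computed in linear
  amplitude or in dB is genuinely open; the dB convention was chosen
  because ILDs are reported in dB and the resulting broadband value is
  scale-equivariant, and it is fixed throughout the package.
* Magnitude spectra use a zero-padded FFT to the next power of two at or
  above four times the impulse-response length, so dB values are
  bit-stable across calls.
* A silent ear would give an infinite ILD; `compute_ild()` caps the
  broadband value at +-120 dB, a documented sentinel that monaural grids
  hit by construction.

# Cue freezing

Each freezing operation fixes one cue at a reference value for all
directions and provably leaves the other two untouched:

* `freeze_itd()` shifts the left impulse response by an integer number of
  samples until its peak time equals the right ear's. Synthetic HRIRs are
  built with their first and last 16 taps exactly zero, so these shifts
  move only zeros in and out and the magnitude spectra (hence ILD and
  spectral cues) are preserved bit-for-bit.
* `freeze_ild()` rescales each ear by one scalar so both band-average
  levels equal their mean: spectral shape and timing untouched.
* `freeze_spectrum()` replaces each impulse response by a single-sample
  impulse at its original peak time, scaled to that ear's band-average
  level: flat spectrum, ITD and broadband ILD exactly preserved.
* `make_monaural()` silences the left ear.

The frozen cue is *present at its reference value*, not erased; a frozen
cue can contradict the cues that still vary, which is the point of the
manipulation.

# The synthetic head filter

`make_synthetic_hrtf()` builds an `hrir_grid()` whose cues emulate a
mouse-like head:

* ITDs follow the acoustic path-difference model (`d/c` times the lateral
  sine), imposed as fractional phase delays around a 300 microsecond base
  latency; measured by integer argmax they quantize to within one sample.
* The broadband ILD is an odd, Rayleigh-shaped function of azimuth with
  its peak at 65 degrees, tapering with the cosine of elevation. The peak
  value defaults to 20 dB: per-frequency ILDs in high-frequency bands of
  small mammals reach +-30 dB, and a band-average is necessarily smaller.
* Spectra are assembled from three orthonormal, zero-mean band patterns
  weighted by the direction's unit-vector components. Component 1 is the
  frontal band template (amplified 10-24 and 48-60 kHz, attenuated 25-45
  and 63-76 kHz, +-10 dB at the default 20 dB peak-to-trough depth), so
  frontal spectra carry the template by construction. Because the
  components have equal norms, the Pearson correlation between the ear
  spectra of two directions equals the cosine of their angular
  separation: every direction has a unique spectral signature decaying
  isotropically with distance. (An earlier design normalized components
  to equal *peak* rather than equal norm; Gram-Schmidt then left the
  elevation component with ~15% of the others' energy and the spectral
  code nearly blind to elevation -- equal norms are a requirement, not a
  nicety.)

What the generator does **not** emulate: measurement noise and
across-animal variability of HRTFs, earphone cross-talk, pinna movement,
front-back spectral asymmetries beyond the component model, and any
distance cues. Tests passing on this generator therefore validate the
*analysis chain*, not the acoustics of any particular animal.

# The simulated neurons

A neuron's expected spike count in the 15 ms analysis window is

```
lambda = (baseline + gain * (w_spec * spec_drive + w_ild * ild_drive)) * window
```

with `spec_drive` the rectified Pearson correlation between the neuron's
frequency template and the contralateral-ear input spectrum, raised to a
sharpness exponent, and `ild_drive` a monotonic sigmoid of the broadband
ILD. The RF *emerges* from the cues: an early design multiplied a fixed
Kent-shaped envelope by the cue drive, but any such envelope survives
every cue manipulation (a constant drive only rescales it), which
contradicts the defining observations the generator must reproduce --
frozen spectra flattening frontal RFs, monaural-plus-frozen-spectrum
stimulation erasing all RFs. The additive drive model reproduces both
mechanically, because freezing flows through the measured cues of the
(frozen) grid rather than through any special-casing.

Choices worth knowing:

* Templates are matched to the head filter at the neuron's preferred
  direction, so `spec_drive` is a bump centered there for *any* azimuth
  (its e^(-1/2) radius matches `radius_from_kappa()` when the sharpness
  equals the nominal Kent concentration). This is also the biological
  story the STRF analysis tests: frontal neurons' frequency tuning
  matches the frontal head filter.
* Spectral and ILD drives combine additively; nothing in the underlying
  protocol constrains sum versus product, and the additive form keeps a
  pure-ILD neuron meaningful when spectra are frozen.
* The ILD sigmoid (threshold 5 dB, slope 3 dB) is monotonic, matching the
  sigmoid ILD codes of midbrain nuclei; with frozen spectra, ILD-driven
  neurons peak where the grid's ILD peaks.
* Counts are negative-binomial with mean `lambda` and variance
  `phi * lambda` (default `phi = 5`, the scale of measured midbrain
  overdispersion): quasi-Poisson moments realized by a proper integer
  distribution; `phi = 1` draws exact Poisson.
* The population generator (`make_population()`) places neurons along
  1.6 mm of the anteroposterior axis with azimuth
  `14 + 58 * position + N(0, 19)` degrees: the configured slope, offset
  and scatter of the emulated topographic map. The 1.6 mm extent keeps
  azimuths inside the +-144 degree stimulus grid even at 2 SD of
  scatter; with a longer axis the grid edge clips the map and the
  *realized* slope is no longer the configured one. The ILD weight
  cross-fades up to 0.15 by 90 degrees azimuth; the RF radius grows as
  `15 + 0.21 * azimuth` degrees, so the concentration `kappa` falls
  laterally.
* All randomness flows from explicit seeds (`with_seed` isolation); the
  caller's RNG state is never disturbed, and identical seeds give
  byte-identical pipeline artifacts.

# Response statistics

Spike counts are taken in the half-open 5-20 ms post-onset window (a
spike at exactly 20 ms is excluded), the fast-response window of midbrain
auditory neurons; slow responders are out of scope. Significance uses
`p = 1 - CDF(N)` with a moment-matched negative binomial (mean from the
pre-stimulus window scaled to the same exposure, variance `phi` times the
mean): quasi-Poisson is a moment model without a distribution, and the
negative binomial realizes those moments while reducing to the exact
Poisson tail at `phi = 1`. The baseline window is the 50 ms before onset,
a package choice recorded in the run configuration. Overdispersion is
estimated as variance over mean per condition, or pooled across
directions via Pearson residuals for fitting.

# Kent RF fitting

The rate model is `baseline + amplitude * Kent(direction)`, all four
shape parameters plus the orthonormal axis triple fitted jointly by
maximizing the same negative-binomial quasi-likelihood with a plug-in
`phi`. Numerical choices:

* Constraints by smooth reparameterization: `kappa = exp(u)` and
  `beta = kappa / 4 * logistic(v)`, enforcing the stability restriction
  `4 beta < kappa`; center bounded to azimuth +-144, elevation 0-90
  (top-Z).
* Multi-start from the highest-mean directions (ties to the lowest
  index); L-BFGS-B with numerical gradients; errors from the numerically
  differentiated Hessian at the optimum. Non-convergent fits are flagged
  and excluded, never silently kept.
* Model selection: `BIC = -2 logL + k log n` with `k = 7` against a flat
  single-rate model with `k = 1`, `n` = direction x trial observations.
  The BIC sample-size convention and the exact quasi-likelihood form are
  package choices (recorded here and in output metadata); the protocol
  this emulates states only that BIC comparison against a flat
  distribution defines RF significance.
* The radius `rho = acos(1 - 1/(2 kappa))` is the e^(-1/2) contour of
  the beta = 0 Kent shape, clipped at 90 degrees for `kappa <= 0.5`.

The topographic map is a chi-square line fit of fitted azimuth against
anatomical position with per-point errors
`sqrt(stat^2 + systematic^2)`; the 19 degree systematic term is the
quadrature combination of pointing-error sources (eye movement ~3,
pinna movement ~13, across-animal head-filter variability ~14 degrees)
that statistical errors cannot see. Without it the chi-square per degree
of freedom is grossly inflated; with it, near 1 on calibrated
simulations.

# Similarity and STRF analyses

The cosine similarity index mean-subtracts, unit-normalizes, then takes
the inner product (that order, fixed); errors propagate per-direction
Poisson count errors to first order, with a trial-bootstrap cross-check.
The control SI (same stimulus, independent noise) must exceed zero at
one-sided `p < 0.01` for a neuron to count as reproducible; losses
`1 - SI/SI_control` are then interpretable. Frontal/lateral summaries
split at 45 degrees azimuth (cue freezing) and 35 degrees (STRF groups,
balancing group sizes), both exposed in `run_config()`.

STRFs are spike-triggered averages on the 10 ms pattern grid, lags 1-10
(patterns 10-100 ms before the spike bin; the simultaneous bin is
excluded). Bins with several spikes weight their preceding patterns by
the count. The per-frequency stimulus mean `M` is computed from the
realized patterns per ear, and each pixel's two-sided binomial test uses
the Bonferroni factor `N_pixels = 2 x 48 x 10 = 960` so the whole STA has
family-wise level 0.001. Neurons with fewer than 20 spikes are refused,
not estimated.

# Problem sizes and runtime

The shipped tests and the acceptance script run the full chain at the
protocol's own scales where that matters scientifically -- 100 simulated
neurons at 30 trials x 85 directions for map recovery, 40 neurons for the
cue-freezing structure, 2-minute x 20-repeat chords for STRFs -- and at
reduced scales (shorter chords, fewer neurons) for plumbing checks where
only correctness, not statistics, is at stake. A full map recovery takes
a few minutes on one core; everything else is seconds.

# Known limitations

* The generator's neurons are rate models with a single latency kernel;
  no adaptation, no locomotion state, no visuoauditory interaction.
* Monotonic-ILD neurons make extreme-lateral RF centers slightly
  attracted toward the ILD maximum; with the default weights this bias
  is a few degrees, well inside the 19 degree systematic budget, but it
  is a real property of the model class, not of the fitter.
* The HRIR container is a JSON layout (with matching WAV and TSV
  writers); standards like SOFA are deliberately out of scope, though the
  grid representation was designed so an adapter only needs to fill
  `hrir_grid()`.
* The chord's 48-tone ladder starts at 5 kHz with 12 tones per octave,
  putting tone 48 at ~75.5 kHz rather than exactly 80 kHz; a 48-tone,
  12-per-octave ladder cannot have both endpoints on 5 and 80 kHz, and
  the ladder (not the bracket) was taken as primary.
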