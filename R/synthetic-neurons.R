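#' Cue summary of an HRIR grid for response simulation
#'
#' Precomputes, once per grid, everything a simulated neuron's drive
#' depends on: per-direction broadband ILD, the contralateral (right) ear
#' log-magnitude band spectrum, and direction unit vectors. Frozen-cue
#' grids produce frozen cue summaries, so simulated responses inherit the
#' stimulus manipulations mechanically rather than by special-casing.
#'
#' @param grid an [hrir_grid()].
#' @return list with `directions`, `unit` (world vectors), `ild_db`,
#'   `spectra_db` (direction x band-bin matrix, right ear), `frequency`.
#' @export
cue_summary <- function(grid) {
  sp <- grid_spectra(grid)
  ct <- compute_ild(grid)
  list(directions = grid$directions,
       unit = direction_to_unit(grid$directions$azimuth,
                                grid$directions$elevation, grid$frame),
       ild_db = ct$ild_db,
       spectra_db = sp$right_db,
       frequency = sp$frequency)
}

#' Construct a simulated auditory neuron
#'
#' A rate model in which a spatially restricted receptive field (RF)
#' emerges from two cue-driven inputs, combined additively with weights
#' `w_spec` and `w_ild`:
#'
#' * **spectral-template drive**: the Pearson correlation between the
#'   neuron's frequency template and the contralateral-ear input spectrum,
#'   rectified at zero and raised to the power `sharpness`. With templates
#'   matched to the head filter at the neuron's preferred direction this
#'   is a smooth bump centered on that direction; a flat input spectrum
#'   (spectrum freezing) drives it to zero everywhere.
#' * **ILD drive**: a sigmoid of the broadband interaural level
#'   difference, `plogis((ILD - ild_threshold) / ild_slope)` -- monotonic,
#'   not tuned, as for midbrain ILD-sensitive neurons. Freezing the ILD
#'   at zero (or removing one ear) makes it direction-independent.
#'
#' Expected spike count in the analysis window is
#' `(baseline_rate + gain * (w_spec * spec_drive + w_ild * ild_drive)) * window`,
#' and trial counts are drawn with mean `lambda` and variance
#' `overdispersion * lambda` (negative-binomial moment matching;
#' `overdispersion = 1` gives exact Poisson draws).
#'
#' The nominal RF is summarized by Kent-distribution parameters
#' (`azimuth`, `elevation`, `kappa`): `sharpness = kappa` makes the
#' spectral bump's e^(-1/2) radius match [radius_from_kappa()].
#'
#' @param azimuth,elevation RF center, front-Z degrees.
#' @param kappa nominal Kent concentration (> 0); also the template
#'   sharpness exponent.
#' @param w_spec,w_ild nonnegative drive weights (must not both be 0).
#' @param template frequency template (vector over band bins) and
#' @param template_frequency its frequency axis, Hz.
#' @param baseline_rate,gain spontaneous and driven rate, Hz.
#' @param overdispersion variance-to-mean ratio phi (>= 1).
#' @param ild_threshold,ild_slope sigmoid parameters, dB.
#' @param latency_peak peak of the response-latency kernel, seconds.
#' @param ap_position anteroposterior anatomical position, mm (optional).
#' @return object of class `"synthetic_neuron"`.
#' @export
synthetic_neuron <- function(azimuth, elevation, kappa = 10,
                             w_spec = 1, w_ild = 0,
                             template = NULL, template_frequency = NULL,
                             baseline_rate = 5, gain = 150,
                             overdispersion = 5,
                             ild_threshold = 5, ild_slope = 3,
                             latency_peak = 0.012,
                             ap_position = NA_real_) {
  if (w_spec < 0 || w_ild < 0 || w_spec + w_ild <= 0) {
    stop("drive weights must be nonnegative and not both zero", call. = FALSE)
  }
  if (overdispersion < 1) {
    stop("`overdispersion` must be >= 1", call. = FALSE)
  }
  if (kappa <= 0) stop("`kappa` must be > 0", call. = FALSE)
  structure(list(azimuth = azimuth, elevation = elevation, kappa = kappa,
                 beta = 0, w_spec = w_spec, w_ild = w_ild,
                 template = template, template_frequency = template_frequency,
                 baseline_rate = baseline_rate, gain = gain,
                 overdispersion = overdispersion,
                 ild_threshold = ild_threshold, ild_slope = ild_slope,
                 latency_peak = latency_peak, ap_position = ap_position),
            class = "synthetic_neuron")
}

#' Idealized frequency template of a simulated neuron
#'
#' The synthetic head filter's spectral pattern at a preferred direction
#' (the component patterns weighted by the direction's unit vector): a
#' neuron carrying this template has frequency tuning matched to the
#' head filter for sound from that direction, the configuration in which
#' spectral cues alone can pinpoint the direction.
#'
#' @param spec a [synthetic_hrtf_spec()].
#' @param frequency band-bin frequency axis, Hz (from [cue_summary()] of
#'   a grid generated with the same spec).
#' @param azimuth,elevation preferred direction, front-Z degrees.
#' @return numeric template over the band bins.
#' @export
neuron_template <- function(spec, frequency, azimuth, elevation) {
  comps <- spectral_components(spec, frequency)
  u <- direction_to_unit(azimuth, elevation, "front-z")
  as.numeric(comps %*% as.numeric(u))
}

# Direction-wise drives and expected window counts for one neuron.
neuron_rates <- function(neuron, cues, window_length = 0.015) {
  n <- nrow(cues$spectra_db)
  spec_drive <- numeric(n)
  if (neuron$w_spec > 0) {
    if (is.null(neuron$template)) {
      stop("neuron has w_spec > 0 but no frequency template", call. = FALSE)
    }
    tpl <- neuron$template
    if (stats::sd(tpl) > 1e-12) {
      for (i in seq_len(n)) {
        s <- cues$spectra_db[i, ]
        if (stats::sd(s) > 1e-9) {
          spec_drive[i] <- max(0, stats::cor(tpl, s))^neuron$kappa
        }
      }
    }
  }
  ild_drive <- stats::plogis((cues$ild_db - neuron$ild_threshold) /
                               neuron$ild_slope)
  drive <- neuron$w_spec * spec_drive + neuron$w_ild * ild_drive
  rate <- neuron$baseline_rate + neuron$gain * drive
  list(rate = rate, lambda = rate * window_length,
       spec_drive = spec_drive, ild_drive = ild_drive)
}

# Overdispersed count draws: mean lambda, variance phi * lambda.
rcounts_overdispersed <- function(n, lambda, phi) {
  if (phi <= 1 + 1e-12) {
    stats::rpois(n, lambda)
  } else {
    stats::rnbinom(n, size = lambda / (phi - 1), mu = lambda)
  }
}

#' Simulate one neuron's spike counts for a stimulus
#'
#' For a [synthesize_vas()] / [synthesize_ild_trial()] stereo stimulus the
#' cues are measured from the waveforms themselves (smoothed FFT spectra
#' and broadband level difference), so any upstream manipulation of the
#' stimulus flows into the response; for a [generate_random_chord()]
#' stimulus a linear-nonlinear model with the neuron's spectro-temporal
#' kernel is used (see [simulate_chord_response()]).
#'
#' @param neuron a [synthetic_neuron()].
#' @param stimulus a `"stereo_stimulus"` or `"chord_stimulus"`.
#' @param seed integer seed.
#' @param n_trials count draws for a stereo stimulus.
#' @param window_length analysis-window length, seconds.
#' @return integer counts (stereo) or per-bin counts (chord).
#' @export
simulate_neuron_response <- function(neuron, stimulus, seed, n_trials = 1,
                                     window_length = 0.015) {
  if (inherits(stimulus, "chord_stimulus")) {
    return(simulate_chord_response(neuron, stimulus, seed)$counts)
  }
  stopifnot(inherits(stimulus, "stereo_stimulus"))
  cues <- stimulus_cues(stimulus, neuron$template_frequency)
  lam <- neuron_rates(neuron, cues, window_length)$lambda
  with_seed(seed,
            rcounts_overdispersed(n_trials, lam, neuron$overdispersion))
}

# Waveform-level cue measurement: log-magnitude spectra interpolated onto
# the template frequency axis and smoothed (running mean over 9 bins) to
# tame periodogram fluctuation; broadband ILD as dB-average difference.
stimulus_cues <- function(stimulus, frequency) {
  if (is.null(frequency)) stop("template frequency axis required", call. = FALSE)
  spec_db <- function(x) {
    nfft <- next_pow2(length(x))
    X <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))[seq_len(nfft %/% 2 + 1)]
    f <- (seq_along(X) - 1) * stimulus$sample_rate / nfft
    db <- 20 * log10(pmax(X, 1e-12))
    sm <- stats::filter(db, rep(1 / 9, 9), sides = 2)
    sm[is.na(sm)] <- db[is.na(sm)]
    stats::approx(f, as.numeric(sm), xout = frequency, rule = 2)$y
  }
  r <- spec_db(stimulus$right)
  l <- if (all(stimulus$left == 0)) rep(-240, length(frequency))
       else spec_db(stimulus$left)
  list(directions = data.frame(azimuth = stimulus$direction[1],
                               elevation = stimulus$direction[2]),
       unit = NULL,
       ild_db = clamp(mean(r) - mean(l), -120, 120),
       spectra_db = matrix(r, nrow = 1),
       frequency = frequency)
}

#' Generate a simulated neural population with a topographic map
#'
#' Places `n_neurons` along the anteroposterior (A-P) axis and assigns RF
#' azimuths `map_offset + map_slope * position + jitter`, emulating a
#' topographic map with scatter. Drive weights cross-fade with azimuth
#' (frontal neurons rely on the spectral template, lateral neurons
#' increasingly on the ILD sigmoid) and the nominal RF radius grows with
#' azimuth, so concentration `kappa` falls.
#'
#' @param n_neurons population size.
#' @param map_slope degrees of azimuth per mm of A-P position.
#' @param map_offset degrees at the A-P origin.
#' @param ap_range `c(min, max)` A-P extent, mm.
#' @param jitter_sd SD of azimuth scatter around the map line, degrees.
#' @param elevation_sd SD of the half-normal elevation distribution, degrees.
#' @param hrtf_spec the [synthetic_hrtf_spec()] whose head filter the
#'   neurons' templates are matched to.
#' @param w_ild_max,w_ild_mid,w_ild_width cross-fade of the ILD weight:
#'   `w_ild = w_ild_max * plogis((azimuth - w_ild_mid) / w_ild_width)`.
#' @param radius_offset,radius_slope nominal RF radius (degrees) as a
#'   linear function of azimuth.
#' @param overdispersion,baseline_rate,gain,ild_threshold,ild_slope passed
#'   to [synthetic_neuron()].
#' @param seed integer seed.
#' @return object of class `"synthetic_population"`: list of neurons plus
#'   a `truth` data.frame (one row per neuron) as an attribute-free field.
#' @export
make_population <- function(n_neurons, map_slope = 58, map_offset = 14,
                            ap_range = c(0, 1.6), jitter_sd = 19,
                            elevation_sd = 8,
                            hrtf_spec = synthetic_hrtf_spec(),
                            w_ild_max = 0.15, w_ild_mid = 45, w_ild_width = 15,
                            radius_offset = 15, radius_slope = 0.21,
                            overdispersion = 5, baseline_rate = 5, gain = 150,
                            ild_threshold = 5, ild_slope = 3, seed = 1) {
  if (n_neurons < 1) stop("`n_neurons` must be >= 1", call. = FALSE)
  draws <- with_seed(seed, {
    ap <- stats::runif(n_neurons, ap_range[1], ap_range[2])
    jit <- stats::rnorm(n_neurons, 0, jitter_sd)
    el <- pmin(abs(stats::rnorm(n_neurons, 0, elevation_sd)), 25)
    list(ap = ap, jit = jit, el = el)
  })
  az <- clamp(map_offset + map_slope * draws$ap + draws$jit, -144, 144)
  rho <- clamp(radius_offset + radius_slope * pmax(az, 0), 5, 80)
  kappa <- 1 / (2 * (1 - cos(deg2rad(rho))))
  w_ild <- w_ild_max * stats::plogis((az - w_ild_mid) / w_ild_width)

  # template frequency axis matches the grids this spec generates
  nfft <- next_pow2(4L * hrtf_spec$ir_length)
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * hrtf_spec$sample_rate / nfft
  freq <- freq[freq >= hrtf_spec$band[1] & freq <= hrtf_spec$band[2]]
  comps <- spectral_components(hrtf_spec, freq)

  neurons <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    u <- as.numeric(direction_to_unit(az[i], draws$el[i], "front-z"))
    neurons[[i]] <- synthetic_neuron(
      azimuth = az[i], elevation = draws$el[i], kappa = kappa[i],
      w_spec = 1 - w_ild[i], w_ild = w_ild[i],
      template = as.numeric(comps %*% u), template_frequency = freq,
      baseline_rate = baseline_rate, gain = gain,
      overdispersion = overdispersion,
      ild_threshold = ild_threshold, ild_slope = ild_slope,
      ap_position = draws$ap[i])
  }
  structure(list(
    neurons = neurons,
    truth = data.frame(neuron = seq_len(n_neurons), ap_position = draws$ap,
                       azimuth = az, elevation = draws$el, kappa = kappa,
                       w_spec = 1 - w_ild, w_ild = w_ild)),
    class = "synthetic_population")
}

#' Simulate population spike counts on a stimulus grid
#'
#' Draws trial-by-trial spike counts for every neuron and direction of a
#' (possibly cue-frozen) HRIR grid, for the 5-20 ms analysis window and a
#' pre-stimulus spontaneous window.
#'
#' @param population a [make_population()] object.
#' @param grid an [hrir_grid()] (any cue-frozen variant).
#' @param n_trials trials per direction.
#' @param seed integer seed.
#' @param window_length evoked analysis-window length, seconds.
#' @param spont_length spontaneous (pre-stimulus) window length, seconds.
#' @return list with `counts` (neuron x direction x trial), `spont`
#'   (neuron x direction x trial), `lambda` (neuron x direction expected
#'   window counts), `directions`.
#' @export
simulate_population_counts <- function(population, grid, n_trials = 30,
                                       seed = 1, window_length = 0.015,
                                       spont_length = 0.05) {
  stopifnot(inherits(population, "synthetic_population"))
  cues <- cue_summary(grid)
  nn <- length(population$neurons)
  nd <- nrow(cues$directions)
  counts <- array(0L, c(nn, nd, n_trials))
  spont <- array(0L, c(nn, nd, n_trials))
  lambda <- matrix(0, nn, nd)
  for (i in seq_len(nn)) {
    nrn <- population$neurons[[i]]
    lam <- neuron_rates(nrn, cues, window_length)$lambda
    lambda[i, ] <- lam
    lam_s <- nrn$baseline_rate * spont_length
    draws <- with_seed(derive_seed(seed, i), {
      list(ev = rcounts_overdispersed(nd * n_trials, rep(lam, n_trials),
                                      nrn$overdispersion),
           sp = rcounts_overdispersed(nd * n_trials, lam_s,
                                      nrn$overdispersion))
    })
    counts[i, , ] <- draws$ev
    spont[i, , ] <- draws$sp
  }
  list(counts = counts, spont = spont, lambda = lambda,
       directions = cues$directions,
       window_length = window_length, spont_length = spont_length)
}
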