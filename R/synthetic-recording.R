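#' Simulate a neuron's response to a dynamic random chord stimulus
#'
#' Linear-nonlinear (LN) Poisson model: each 10-ms pattern bin's firing
#' rate is a rectified linear function of the mean-subtracted tone
#' patterns over the preceding `lookback` bins, weighted by the neuron's
#' spectro-temporal kernel. The kernel's frequency profile is the
#' neuron's template sampled at the tone frequencies; its contralateral
#' and ipsilateral ears are related by a binaural sign factor that fades
#' from +1 (frontal, symmetric ears) to -1 (lateral, anti-symmetric) with
#' the neuron's RF azimuth, and its time course peaks 10-20 ms before the
#' spike.
#'
#' @param neuron a [synthetic_neuron()].
#' @param chord a [generate_random_chord()] stimulus.
#' @param seed integer seed.
#' @param chord_gain rate modulation per unit kernel drive, Hz.
#' @param baseline_rate chord-stimulus baseline rate, Hz (defaults to a
#'   driven rate well above the spatial-noise baseline so spike counts are
#'   realistic for a 40-minute stimulus).
#' @return list with `counts` (spikes per 10-ms bin over all repeats),
#'   `kernel` (2 x n_tones x lookback ground-truth array, ears =
#'   ipsi/left, contra/right), `rate` (per-bin rate, one presentation).
#' @export
simulate_chord_response <- function(neuron, chord, seed, chord_gain = 6,
                                    baseline_rate = 30) {
  stopifnot(inherits(chord, "chord_stimulus"))
  kern <- chord_kernel(neuron, chord)
  np <- nrow(chord$left)
  lookback <- dim(kern)[3]
  drive <- numeric(np)
  sl <- sweep(chord$left, 2, colMeans(chord$left))
  sr <- sweep(chord$right, 2, colMeans(chord$right))
  for (k in seq_len(lookback)) {
    idx <- ((seq_len(np) - 1 - k) %% np) + 1 # repeats tile circularly
    drive <- drive + sl[idx, , drop = FALSE] %*% kern[1, , k] +
                     sr[idx, , drop = FALSE] %*% kern[2, , k]
  }
  rate <- pmax(0, baseline_rate + chord_gain * as.numeric(drive))
  lam <- rep(rate * chord$pattern_duration, chord$n_repeats)
  counts <- with_seed(seed, stats::rpois(length(lam), lam))
  list(counts = counts, kernel = kern, rate = rate)
}

# Ground-truth spectro-temporal kernel of a simulated neuron.
chord_kernel <- function(neuron, chord, lookback = 10) {
  if (is.null(neuron$template)) {
    stop("neuron needs a frequency template for chord simulation",
         call. = FALSE)
  }
  ftone <- chord$frequencies
  prof <- stats::approx(neuron$template_frequency, neuron$template,
                        xout = ftone, rule = 2)$y
  prof <- prof / max(abs(prof))
  lagw <- numeric(lookback)
  lagw[1:3] <- c(0.6, 1, 0.25) # strongest 10-20 ms before the spike
  bsign <- 1 - 2 * stats::plogis((neuron$azimuth - 35) / 10)
  kern <- array(0, c(2, length(ftone), lookback))
  for (k in seq_len(lookback)) {
    kern[2, , k] <- prof * lagw[k]
    kern[1, , k] <- bsign * prof * lagw[k]
  }
  kern
}

#' Simulate a spike-time recording for a stimulus grid
#'
#' Expands [simulate_population_counts()] draws into spike times and
#' stimulus events, in the same tabular shapes the real-data path reads
#' (see [write_spike_table()] / [write_event_table()]): stimuli presented
#' every `interval` seconds in direction-major order, evoked spikes placed
#' in the 5-20 ms window with a latency density peaking at the neuron's
#' `latency_peak`, spontaneous spikes uniform in the pre-stimulus window.
#'
#' @param population a [make_population()] object.
#' @param grid an [hrir_grid()].
#' @param n_trials trials per direction.
#' @param seed integer seed.
#' @param interval stimulus onset asynchrony, seconds.
#' @param condition condition label for the event table.
#' @return list with `spikes` (data.frame `neuron`, `time_s`), `events`
#'   (data.frame `time_s`, `direction`, `condition`, `trial`), `sim` (the
#'   underlying count simulation), `window` = c(0.005, 0.020).
#' @export
simulate_recording <- function(population, grid, n_trials = 10, seed = 1,
                               interval = 2, condition = "original") {
  sim <- simulate_population_counts(population, grid, n_trials, seed)
  nd <- nrow(sim$directions)
  events <- data.frame(
    time_s = interval * (seq_len(nd * n_trials) - 1) + interval,
    direction = rep(seq_len(nd), each = n_trials),
    condition = condition,
    trial = rep(seq_len(n_trials), times = nd))
  win <- c(0.005, 0.020)
  spk_n <- integer(0)
  spk_t <- numeric(0)
  for (i in seq_along(population$neurons)) {
    nrn <- population$neurons[[i]]
    times_i <- with_seed(derive_seed(seed, 7L, i), {
      out <- numeric(0)
      for (e in seq_len(nrow(events))) {
        d <- events$direction[e]
        tr <- events$trial[e]
        n_ev <- sim$counts[i, d, tr]
        if (n_ev > 0) {
          out <- c(out, events$time_s[e] +
                     sample_latency(n_ev, nrn$latency_peak, win))
        }
        n_sp <- sim$spont[i, d, tr]
        if (n_sp > 0) {
          out <- c(out, events$time_s[e] -
                     stats::runif(n_sp, 0, sim$spont_length))
        }
      }
      sort(out)
    })
    spk_n <- c(spk_n, rep(i, length(times_i)))
    spk_t <- c(spk_t, times_i)
  }
  list(spikes = data.frame(neuron = spk_n, time_s = spk_t),
       events = events, sim = sim, window = win)
}

# Latencies from an alpha-function density (t/peak) * exp(1 - t/peak),
# truncated to the analysis window, drawn by inverse-CDF on a fine grid.
sample_latency <- function(n, peak, window) {
  tt <- seq(window[1], window[2] - 1e-6, length.out = 512) # keep half-open
  dens <- (tt / peak) * exp(1 - tt / peak)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, tt, xout = stats::runif(n), rule = 2)$y
}
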