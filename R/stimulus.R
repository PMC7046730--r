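#' Virtual auditory space (VAS) stimulus synthesis
#'
#' Synthesizes the binaural waveform for one virtual source direction: a
#' white-noise burst (default 100 ms) band-limited to the grid's analysis
#' band, with linear onset/offset tapers (default 5 ms), filtered per ear
#' by the direction's head-related impulse response (including phase). A
#' fresh noise pattern is generated for every call ("non-frozen" noise),
#' controlled by `noise_seed` so runs are reproducible.
#'
#' The direction must lie exactly on the grid; nearest-neighbour
#' substitution is refused.
#'
#' @param azimuth,elevation source direction in the grid's frame (degrees).
#' @param grid an [hrir_grid()].
#' @param noise_seed integer seed for the noise pattern.
#' @param inverse_filter optional FIR flattening filter for the playback
#'   chain (identity when `NULL`; in a hardware rig this is the zero-phase
#'   inverse of the speaker-and-earphone response).
#' @param duration,taper burst duration and linear taper length, seconds.
#' @param condition condition label stored with the stimulus.
#' @return object of class `"stereo_stimulus"`: list with `left`, `right`
#'   waveforms (length `duration * sample_rate`), `sample_rate`,
#'   `direction`, `condition`, `noise_seed`.
#' @export
synthesize_vas <- function(azimuth, elevation, grid, noise_seed,
                           inverse_filter = NULL,
                           duration = 0.1, taper = 0.005,
                           condition = "original") {
  stopifnot(inherits(grid, "hrir_grid"))
  i <- direction_index(grid, azimuth, elevation)
  n <- round(duration * grid$sample_rate)
  src <- noise_burst(n, grid$sample_rate, grid$band, taper, noise_seed)
  if (!is.null(inverse_filter)) {
    src <- conv_full(src, inverse_filter)[seq_len(n)]
  }
  structure(
    list(left = conv_full(src, grid$left[i, ])[seq_len(n)],
         right = conv_full(src, grid$right[i, ])[seq_len(n)],
         sample_rate = grid$sample_rate,
         duration = duration, taper = taper,
         direction = c(azimuth = azimuth, elevation = elevation),
         condition = condition, noise_seed = as.integer(noise_seed)),
    class = "stereo_stimulus")
}

# Band-limited, linearly tapered white-noise burst (unit RMS before taper).
noise_burst <- function(n, sample_rate, band, taper, seed) {
  x <- with_seed(seed, stats::rnorm(n))
  x <- band_limit(x, sample_rate, band)
  x <- x / stats::sd(x)
  apply_taper(x, round(taper * sample_rate))
}

# Zero-phase brick-wall band limitation via FFT masking.
band_limit <- function(x, sample_rate, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) * sample_rate / n
  f <- pmin(f, sample_rate - f) # two-sided spectrum frequencies
  X <- stats::fft(x)
  X[f < band[1] | f > band[2]] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

apply_taper <- function(x, k) {
  if (k > 0) {
    ramp <- seq(0, 1, length.out = k + 1)[-1]
    x[seq_len(k)] <- x[seq_len(k)] * ramp
    x[(length(x) - k + 1):length(x)] <- x[(length(x) - k + 1):length(x)] * rev(ramp)
  }
  x
}

#' Extended-ILD stimulus schedule
#'
#' Flat-spectrum 100-ms noise bursts whose interaural level difference
#' (ILD) is stepped through -40 to +40 dB in 2 dB increments (41 levels),
#' each repeated `n_repeats` times, in an order randomized by `seed`. The
#' set is returned as a schedule (level and per-trial noise seed); waveform
#' synthesis is deferred to [synthesize_ild_trial()] so that an 85-minute
#' stimulus need not be held in memory.
#'
#' @param seed master seed controlling trial order and per-trial noise.
#' @param n_repeats presentations per ILD level.
#' @param levels ILD levels in dB (right minus left).
#' @param sample_rate,duration,taper waveform parameters (seconds).
#' @param band reproduced frequency band, Hz.
#' @return object of class `"ild_set"`: data.frame schedule with `trial`,
#'   `ild_db`, `noise_seed`, plus waveform parameters as attributes.
#' @export
build_extended_ild_set <- function(seed, n_repeats = 30,
                                   levels = seq(-40, 40, by = 2),
                                   sample_rate = 5e5, duration = 0.1,
                                   taper = 0.005, band = c(5000, 80000)) {
  sched <- data.frame(ild_db = rep(levels, each = n_repeats))
  ord <- with_seed(derive_seed(seed, 1), sample.int(nrow(sched)))
  sched <- sched[ord, , drop = FALSE]
  sched$trial <- seq_len(nrow(sched))
  sched$noise_seed <- vapply(sched$trial, function(t) derive_seed(seed, 2, t),
                             integer(1))
  rownames(sched) <- NULL
  structure(sched[, c("trial", "ild_db", "noise_seed")],
            sample_rate = sample_rate, duration = duration, taper = taper,
            band = band, class = c("ild_set", "data.frame"))
}

#' @rdname build_extended_ild_set
#' @param set an `"ild_set"` schedule.
#' @param trial trial number to synthesize.
#' @return `synthesize_ild_trial()`: a `"stereo_stimulus"` whose ears carry
#'   gains of +-ILD/2 dB around a common flat-spectrum burst.
#' @export
synthesize_ild_trial <- function(set, trial) {
  stopifnot(inherits(set, "ild_set"))
  row <- set[set$trial == trial, ]
  if (nrow(row) != 1L) stop("unknown trial", call. = FALSE)
  sr <- attr(set, "sample_rate")
  n <- round(attr(set, "duration") * sr)
  src <- noise_burst(n, sr, attr(set, "band"), attr(set, "taper"),
                     row$noise_seed)
  structure(
    list(left = src * 10^(-row$ild_db / 40),
         right = src * 10^(row$ild_db / 40),
         sample_rate = sr, duration = attr(set, "duration"),
         taper = attr(set, "taper"),
         direction = c(azimuth = NA_real_, elevation = NA_real_),
         condition = "extended_ild", ild_db = row$ild_db,
         noise_seed = row$noise_seed),
    class = "stereo_stimulus")
}

#' Dynamic random chord stimulus
#'
#' Binary tone-pattern matrices for spectro-temporal receptive field
#' estimation: 48 tones from 5 to 80 kHz at 12 per octave, presented in
#' 10-ms patterns (3-ms linear tapers when rendered to audio). In each
#' pattern every tone is independently ON with probability 0.5, and the
#' two ears are statistically independent. One presentation lasts
#' `total_minutes` (12,000 patterns at the 2-minute default) and the same
#' pattern set is repeated `n_repeats` times.
#'
#' @param seed integer seed.
#' @param total_minutes length of one presentation, minutes.
#' @param n_repeats number of repeats of the identical pattern set.
#' @param n_tones,f_low,tones_per_octave tone grid (48 tones from 5 kHz at
#'   12 per octave; the top tone is then `5 * 2^(47/12) ~ 75.5` kHz).
#' @param pattern_duration,taper pattern timing in seconds.
#' @return object of class `"chord_stimulus"`: list with binary matrices
#'   `left`, `right` (`n_patterns x n_tones`), `frequencies` (Hz),
#'   `pattern_duration`, `taper`, `n_repeats`, `seed`.
#' @export
generate_random_chord <- function(seed, total_minutes = 2, n_repeats = 20,
                                  n_tones = 48, f_low = 5000,
                                  tones_per_octave = 12,
                                  pattern_duration = 0.01, taper = 0.003) {
  if (total_minutes <= 0) stop("`total_minutes` must be > 0", call. = FALSE)
  n_patterns <- round(total_minutes * 60 / pattern_duration)
  pats <- with_seed(seed, {
    list(left = matrix(stats::rbinom(n_patterns * n_tones, 1, 0.5),
                       n_patterns, n_tones),
         right = matrix(stats::rbinom(n_patterns * n_tones, 1, 0.5),
                        n_patterns, n_tones))
  })
  structure(
    list(left = pats$left, right = pats$right,
         frequencies = f_low * 2^((seq_len(n_tones) - 1) / tones_per_octave),
         pattern_duration = pattern_duration, taper = taper,
         n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
    class = "chord_stimulus")
}
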