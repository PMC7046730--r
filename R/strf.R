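#' Binaural spectro-temporal receptive field by spike-triggered averaging
#'
#' Spikes are discretized at the 10-ms pattern grid of the random chord
#' stimulus and, for each lag `k = 1..lookback` (pattern starting
#' `k * 10` ms before the spike bin), the count-weighted average of the
#' binary tone patterns preceding each spike is computed per ear. The
#' per-frequency time-average of the realized stimulus, `M` (close to,
#' but not exactly, the nominal 0.5), is subtracted for display and
#' tested against in [sta_significance()].
#'
#' Neurons with fewer than `min_spikes` spikes (default 20) are not
#' analyzable and raise a condition of class `"vasrf_too_few_spikes"`.
#'
#' @param spike_counts spikes per 10-ms bin over the whole presentation
#'   (length = patterns x repeats of `chord`).
#' @param chord a [generate_random_chord()] stimulus.
#' @param lookback number of pattern lags (default 10 = 100 ms).
#' @param min_spikes minimum spike count for analysis.
#' @return object of class `"strf"`: list with `sta` (2 x n_tones x
#'   lookback array of STA minus `M`; ear 1 = ipsi/left, 2 =
#'   contra/right), `sta_raw`, `stim_mean` (2 x n_tones `M`), `n_spikes`,
#'   `n_per_lag`, `frequencies`, `lookback`.
#' @export
compute_sta <- function(spike_counts, chord, lookback = 10, min_spikes = 20) {
  stopifnot(inherits(chord, "chord_stimulus"))
  np <- nrow(chord$left)
  n_bins <- np * chord$n_repeats
  if (length(spike_counts) != n_bins) {
    stop("`spike_counts` must have one entry per 10-ms stimulus bin",
         call. = FALSE)
  }
  n_spikes <- sum(spike_counts)
  if (n_spikes < min_spikes) {
    stop(structure(class = c("vasrf_too_few_spikes", "error", "condition"),
                   list(message = sprintf(
                     "only %d spikes (< %d): neuron not analyzable",
                     n_spikes, min_spikes), call = NULL)))
  }
  nf <- length(chord$frequencies)
  pattern_of_bin <- rep(seq_len(np), chord$n_repeats)
  sta_raw <- array(0, c(2, nf, lookback))
  n_per_lag <- numeric(lookback)
  for (k in seq_len(lookback)) {
    t_idx <- (k + 1):n_bins # bins with a full k-lag history
    w <- spike_counts[t_idx]
    n_per_lag[k] <- sum(w)
    pos <- pattern_of_bin[t_idx - k]
    agg <- rowsum(w, pos) # spikes attributed to each pattern at this lag
    rows <- as.integer(rownames(agg))
    sta_raw[1, , k] <- as.numeric(crossprod(chord$left[rows, , drop = FALSE],
                                            agg)) / n_per_lag[k]
    sta_raw[2, , k] <- as.numeric(crossprod(chord$right[rows, , drop = FALSE],
                                            agg)) / n_per_lag[k]
  }
  stim_mean <- rbind(colMeans(chord$left), colMeans(chord$right))
  sta <- sta_raw - array(rep(stim_mean, lookback), c(2, nf, lookback))
  structure(list(sta = sta, sta_raw = sta_raw, stim_mean = stim_mean,
                 n_spikes = n_spikes, n_per_lag = n_per_lag,
                 frequencies = chord$frequencies, lookback = lookback),
            class = "strf")
}

#' Per-pixel binomial significance of an STA
#'
#' Each STA pixel is the mean of `N` Bernoulli(M) tone states under the
#' null of stimulus-independent spiking, so its binomial CDF value
#' `pbinom(S * N, N, M)` locates it in the null distribution. Pixels
#' above `1 - alpha / N_pixels / 2` are significantly positive (+1),
#' below `alpha / N_pixels / 2` significantly negative (-1); the factor
#' `N_pixels = ears x frequencies x lags` is the Bonferroni correction
#' (960 for the default binaural 48 x 10 STA) and the factor 2 makes the
#' test two-sided, so the whole STA has a family-wise level `alpha`.
#'
#' @param strf a [compute_sta()] result.
#' @param alpha family-wise significance level (default 0.001).
#' @return the `strf` with a `mask` element (2 x n_tones x lookback,
#'   values -1/0/+1) and `n_pixels` added.
#' @export
sta_significance <- function(strf, alpha = 0.001) {
  stopifnot(inherits(strf, "strf"))
  dims <- dim(strf$sta_raw)
  n_pixels <- prod(dims)
  thr <- alpha / n_pixels / 2
  mask <- array(0L, dims)
  for (ear in 1:2) {
    for (k in seq_len(strf$lookback)) {
      n <- strf$n_per_lag[k]
      m <- strf$stim_mean[ear, ]
      s <- strf$sta_raw[ear, , k]
      p_cdf <- stats::pbinom(round(s * n), n, m)
      mask[ear, , k] <- ifelse(p_cdf > 1 - thr, 1L,
                               ifelse(p_cdf < thr, -1L, 0L))
    }
  }
  strf$mask <- mask
  strf$n_pixels <- n_pixels
  strf
}

#' Binaural similarity index of an STA
#'
#' Cosine similarity ([cosine_si()] normalization: mean-subtracted,
#' unit-norm inner product) between the flattened ipsilateral and
#' contralateral STA blocks: +1 for symmetric ears, 0 for uncorrelated,
#' -1 for anti-symmetric frequency tuning.
#'
#' @param strf a [compute_sta()] result.
#' @return the BSI (scalar).
#' @export
binaural_si <- function(strf) {
  stopifnot(inherits(strf, "strf"))
  ipsi <- as.numeric(strf$sta[1, , ])
  contra <- as.numeric(strf$sta[2, , ])
  if (stats::sd(ipsi) == 0 || stats::sd(contra) == 0) {
    stop("BSI undefined for a zero-variance STA block", call. = FALSE)
  }
  cosine_si(ipsi, contra)$si
}

#' Population maps of significant STRF structure
#'
#' Splits neurons into frontal and lateral groups by RF azimuth and
#' reports, per STA pixel, the fraction of each group with significantly
#' positive (and negative) structure.
#'
#' @param strfs list of [sta_significance()] results (each with a
#'   `mask`).
#' @param rf_azimuths RF azimuths, degrees (same length as `strfs`).
#' @param split frontal/lateral boundary, degrees (default 35, chosen to
#'   balance group sizes).
#' @return object of class `"population_map"`: list with `frontal` and
#'   `lateral`, each holding `positive`/`negative` fraction arrays and
#'   `n`.
#' @export
population_fraction_map <- function(strfs, rf_azimuths, split = 35) {
  if (length(strfs) != length(rf_azimuths)) {
    stop("one RF azimuth per STRF required", call. = FALSE)
  }
  groups <- list(frontal = which(rf_azimuths < split),
                 lateral = which(rf_azimuths >= split))
  if (any(lengths(groups) == 0)) {
    stop("both azimuth groups must be non-empty", call. = FALSE)
  }
  out <- lapply(groups, function(idx) {
    dims <- dim(strfs[[idx[1]]]$mask)
    pos <- array(0, dims)
    neg <- array(0, dims)
    for (i in idx) {
      pos <- pos + (strfs[[i]]$mask == 1L)
      neg <- neg + (strfs[[i]]$mask == -1L)
    }
    list(positive = pos / length(idx), negative = neg / length(idx),
         n = length(idx))
  })
  structure(out, split = split, class = "population_map")
}
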