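#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate in fixed-width bins aligned to stimulus
#' onset.
#'
#' @param spike_times sorted spike times, seconds.
#' @param event_times stimulus onset times, seconds.
#' @param bin_width bin width, seconds (default 5 ms).
#' @param window peri-stimulus interval `c(start, end)` relative to onset.
#' @return object of class `"psth"`: list with `rate` (Hz per bin),
#'   `bin_centers` (s), `counts` (summed over trials), `n_trials`,
#'   `peak_latency` (center of the maximal bin, s).
#' @export
build_psth <- function(spike_times, event_times, bin_width = 0.005,
                       window = c(-0.05, 0.1)) {
  if (length(event_times) == 0) {
    stop("at least one event is required", call. = FALSE)
  }
  breaks <- seq(window[1], window[2], by = bin_width)
  if (breaks[length(breaks)] < window[2] - 1e-12) {
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  }
  rel <- unlist(lapply(event_times, function(e) {
    s <- spike_times - e
    s[s >= window[1] & s < breaks[length(breaks)]]
  }))
  counts <- if (length(rel)) {
    tabulate(findInterval(rel, breaks, rightmost.closed = FALSE),
             nbins = length(breaks) - 1)
  } else {
    integer(length(breaks) - 1)
  }
  centers <- breaks[-length(breaks)] + bin_width / 2
  structure(list(rate = counts / (length(event_times) * bin_width),
                 bin_centers = centers, counts = counts,
                 n_trials = length(event_times),
                 bin_width = bin_width,
                 peak_latency = centers[which.max(counts)]),
            class = "psth")
}

#' Analysis-window spike counts per trial and direction
#'
#' Counts spikes in a half-open window after each stimulus onset (the
#' default is the 5-20 ms fast-response window: a spike at exactly 20 ms
#' is excluded, one at exactly 5 ms included) and arranges them as a
#' trial x direction integer matrix.
#'
#' @param spike_times one neuron's sorted spike times, seconds.
#' @param events data.frame with `time_s` (onsets) and `direction`
#'   (integer direction index); every direction must have the same number
#'   of trials.
#' @param window half-open count window `[start, end)` relative to onset,
#'   seconds.
#' @return object of class `"response_matrix"`: integer matrix
#'   (trial x direction) with attribute `window`.
#' @export
window_counts <- function(spike_times, events, window = c(0.005, 0.020)) {
  if (is.unsorted(events$time_s)) {
    events <- events[order(events$time_s), ]
  }
  if (any(diff(events$time_s) < diff(window) - 1e-12)) {
    stop("event spacing shorter than the count window", call. = FALSE)
  }
  counts <- vapply(events$time_s, function(e) {
    sum(spike_times >= e + window[1] & spike_times < e + window[2])
  }, numeric(1))
  tab <- table(events$direction)
  n_trials <- unique(as.integer(tab))
  if (length(n_trials) != 1L) {
    stop("all directions must have the same number of trials", call. = FALSE)
  }
  dirs <- sort(unique(events$direction))
  m <- matrix(0L, n_trials, length(dirs))
  for (j in seq_along(dirs)) {
    m[, j] <- as.integer(counts[events$direction == dirs[j]])
  }
  colnames(m) <- dirs
  structure(m, window = window, class = c("response_matrix", class(m)))
}

#' Overdispersion of spike counts
#'
#' The variance-to-mean ratio phi of repeated counts: 1 for a Poisson
#' neuron, larger when trial-to-trial variability is inflated by
#' bursting, state changes, or movement.
#'
#' `estimate_overdispersion()` is the plain sample variance / sample mean
#' of one condition's counts. `pooled_overdispersion()` pools Pearson
#' residuals across the columns of a trial x direction response matrix
#' (each direction has its own mean), the appropriate plug-in for
#' fitting and significance testing.
#'
#' @param counts integer vector (>= 2 values, positive mean).
#' @return phi estimate (dimensionless).
#' @export
estimate_overdispersion <- function(counts) {
  if (length(counts) < 2) stop("need at least 2 counts", call. = FALSE)
  m <- mean(counts)
  if (m <= 0) stop("overdispersion undefined for zero mean", call. = FALSE)
  stats::var(counts) / m
}

#' @rdname estimate_overdispersion
#' @param response_matrix trial x direction count matrix.
#' @export
pooled_overdispersion <- function(response_matrix) {
  m <- colMeans(response_matrix)
  keep <- m > 0
  if (!any(keep)) stop("overdispersion undefined for all-zero matrix",
                       call. = FALSE)
  n_tr <- nrow(response_matrix)
  num <- sum(sweep(response_matrix[, keep, drop = FALSE], 2, m[keep])^2 /
               rep(m[keep], each = n_tr))
  num / (sum(keep) * (n_tr - 1))
}

#' Quasi-Poisson significance test for a spike count
#'
#' Upper-tail test of an observed count `N` against a null with mean
#' `baseline_mean` and variance `phi * baseline_mean`. Quasi-Poisson is a
#' moment model without a distribution, so the tail is evaluated with the
#' moment-matched negative binomial (`phi = 1` reduces to the exact
#' Poisson tail); `p = 1 - CDF(N)`.
#'
#' @param count observed spike count `N` (nonnegative integer).
#' @param baseline_mean null mean count (>= 0).
#' @param phi overdispersion (values < 1 are clamped to 1, with a
#'   message, since sub-Poisson nulls only make the test conservative).
#' @param alpha significance level (default 0.001).
#' @return object of class `"significance_result"`: list with `p_value`,
#'   `phi`, `is_significant`.
#' @export
quasi_poisson_test <- function(count, baseline_mean, phi = 1, alpha = 0.001) {
  if (count < 0) stop("`count` must be nonnegative", call. = FALSE)
  if (baseline_mean < 0) stop("`baseline_mean` must be >= 0", call. = FALSE)
  if (phi < 1) {
    message("phi < 1 clamped to 1 (Poisson)")
    phi <- 1
  }
  p <- if (baseline_mean == 0) {
    as.numeric(count == 0) # any spike is infinitely unlikely under a 0 mean
  } else if (phi <= 1 + 1e-12) {
    1 - stats::ppois(count, baseline_mean)
  } else {
    1 - stats::pnbinom(count, size = baseline_mean / (phi - 1),
                       mu = baseline_mean)
  }
  structure(list(p_value = p, phi = phi,
                 is_significant = p < alpha, alpha = alpha),
            class = "significance_result")
}

#' Auditory-response significance of one neuron
#'
#' Tests the neuron's total evoked spike count (summed over all trials
#' and directions of one condition) against the spontaneous rate scaled
#' to the same total exposure, using [quasi_poisson_test()] with the
#' overdispersion pooled from the evoked counts.
#'
#' @param response_matrix trial x direction evoked counts
#'   ([window_counts()]).
#' @param spont_matrix trial x direction spontaneous-window counts.
#' @param window_length,spont_length lengths (s) of the evoked and
#'   spontaneous windows.
#' @param alpha significance level.
#' @return a `"significance_result"` (see [quasi_poisson_test()]).
#' @export
response_significance <- function(response_matrix, spont_matrix,
                                  window_length = 0.015, spont_length = 0.05,
                                  alpha = 0.001) {
  n_obs <- length(response_matrix)
  baseline <- mean(spont_matrix) * (window_length / spont_length) * n_obs
  phi <- tryCatch(pooled_overdispersion(response_matrix), error = function(e) 1)
  quasi_poisson_test(sum(response_matrix), baseline, max(1, phi), alpha)
}

#' Binomial error for a categorical fraction
#'
#' For `k` of `N` items in a category, the fraction `p = k/N` with
#' standard error `sqrt(p (1 - p) / N)` (binomial), both in percent.
#'
#' @param k category count.
#' @param n total count (>= 1).
#' @return list with `fraction_pct` and `se_pct`.
#' @examples
#' binomial_fraction_se(2016, 3556) # 56.7 +- 0.8 %
#' @export
binomial_fraction_se <- function(k, n) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  p <- k / n
  list(fraction_pct = 100 * p, se_pct = 100 * sqrt(p * (1 - p) / n))
}
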