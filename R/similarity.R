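#' Cosine similarity index between direction-response vectors
#'
#' Treats the per-direction responses as a vector, subtracts the mean,
#' scales to unit norm, and takes the inner product of the two normalized
#' vectors. Identical receptive-field structure gives SI = 1, uncorrelated
#' structure 0, inverted structure -1; the index is invariant to positive
#' affine rescaling of either input.
#'
#' The SI's statistical error is obtained by first-order (delta-method)
#' propagation of the per-direction count errors (Poisson errors of the
#' summed counts, unless supplied); [cosine_si_bootstrap()] offers a
#' trial-resampling cross-check.
#'
#' @param responses_a,responses_b per-direction response vectors (equal
#'   length, e.g. summed 5-20 ms counts over trials at the 85 virtual
#'   directions).
#' @param errors_a,errors_b per-direction errors; defaults to
#'   `sqrt(pmax(responses, 1))` (Poisson, with a floor so empty
#'   directions still carry uncertainty).
#' @return object of class `"similarity_result"`: list with `si`,
#'   `si_error`.
#' @export
cosine_si <- function(responses_a, responses_b,
                      errors_a = NULL, errors_b = NULL) {
  a <- as.numeric(responses_a)
  b <- as.numeric(responses_b)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("responses must be finite", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("similarity undefined for a zero-variance vector", call. = FALSE)
  }
  if (is.null(errors_a)) errors_a <- sqrt(pmax(a, 1))
  if (is.null(errors_b)) errors_b <- sqrt(pmax(b, 1))
  n <- length(a)
  ac <- a - mean(a); bc <- b - mean(b)
  na <- sqrt(sum(ac^2)); nb <- sqrt(sum(bc^2))
  ah <- ac / na; bh <- bc / nb
  si <- sum(ah * bh)
  # d si / d a_i = (bh - si * ah) / ||ac|| after centering projection
  ga <- (bh - si * ah) / na
  gb <- (ah - si * bh) / nb
  ga <- ga - mean(ga)
  gb <- gb - mean(gb)
  se <- sqrt(sum(ga^2 * errors_a^2) + sum(gb^2 * errors_b^2))
  structure(list(si = si, si_error = se, n = n),
            class = "similarity_result")
}

#' @rdname cosine_si
#' @param trials_a,trials_b trial x direction count matrices; trials are
#'   resampled with replacement and the SI of the resampled direction
#'   sums recomputed.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return `cosine_si_bootstrap()`: list with `si` (point estimate from
#'   the full data) and `si_error` (bootstrap SD).
#' @export
cosine_si_bootstrap <- function(trials_a, trials_b, n_boot = 200, seed = 1) {
  point <- cosine_si(colSums(trials_a), colSums(trials_b))$si
  sis <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ia <- sample.int(nrow(trials_a), replace = TRUE)
      ib <- sample.int(nrow(trials_b), replace = TRUE)
      tryCatch(cosine_si(colSums(trials_a[ia, , drop = FALSE]),
                         colSums(trials_b[ib, , drop = FALSE]))$si,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  list(si = point, si_error = stats::sd(sis, na.rm = TRUE))
}

#' Normalized similarity loss for a frozen-cue condition
#'
#' The SI of a frozen-cue condition is normalized by the control SI
#' (same stimulus played twice), `NSI = SI_cue / SI_control`; the loss
#' `1 - NSI` measures how much of the reproducible RF structure the
#' frozen cue was carrying.
#'
#' @param si_cue SI between original and frozen-cue responses.
#' @param si_control SI between original and control responses (> 0;
#'   neurons failing [reproducibility_filter()] are excluded upstream).
#' @return the NSI loss `1 - si_cue / si_control`.
#' @export
nsi_loss <- function(si_cue, si_control) {
  if (any(si_control <= 0)) {
    stop("`si_control` must be > 0 (exclude irreproducible neurons)",
         call. = FALSE)
  }
  1 - si_cue / si_control
}

#' Reproducibility filter on the control similarity
#'
#' One-sided z-test that the control SI is greater than zero at
#' `alpha = 0.01`; only neurons with a reproducible RF pass.
#'
#' @param si_control control SI.
#' @param si_error its propagated error (> 0).
#' @param alpha significance level.
#' @return logical.
#' @export
reproducibility_filter <- function(si_control, si_error, alpha = 0.01) {
  if (any(si_error <= 0)) stop("`si_error` must be > 0", call. = FALSE)
  si_control / si_error > stats::qnorm(1 - alpha)
}

#' Classify the shape of an ILD tuning curve
#'
#' Given mean spike counts at each interaural level difference (ILD) of
#' the extended-ILD stimulus (41 levels, -40..40 dB), tests flatness with
#' a quasi-Poisson chi-square against the pooled mean (`dof = levels - 1`);
#' non-flat neurons (`p < 0.01`) are `"peaked"` if some interior level's
#' rate significantly exceeds the rate at both -40 and +40 dB (one-sided
#' z-tests at `alpha`, Bonferroni-corrected over the interior levels
#' tested), and `"monotonic"` otherwise -- midbrain ILD codes are
#' overwhelmingly sigmoid/monotonic rather than tuned.
#'
#' @param mean_counts mean spike count per ILD level (length >= 3).
#' @param n_trials trials per level (scalar or vector).
#' @param phi overdispersion for the count variance `phi * mu`.
#' @param alpha significance level (default 0.01).
#' @return object of class `"ild_tuning_class"`: list with `class`
#'   (`"flat"`, `"monotonic"`, `"peaked"`), `chi2_flat`, `p_flat`,
#'   `p_peak` (smallest Bonferroni-adjusted peak p-value).
#' @export
ild_tuning_classify <- function(mean_counts, n_trials, phi = 1, alpha = 0.01) {
  k <- length(mean_counts)
  if (k < 3) stop("need at least 3 ILD levels", call. = FALSE)
  if (any(!is.finite(mean_counts))) stop("missing levels", call. = FALSE)
  n_trials <- rep_len(n_trials, k)
  phi <- max(1, phi)
  mbar <- sum(mean_counts * n_trials) / sum(n_trials)
  if (mbar <= 0) stop("all-zero responses", call. = FALSE)
  var_mean <- phi * mbar / n_trials # variance of a level's mean under flatness
  chi2 <- sum((mean_counts - mbar)^2 / var_mean)
  p_flat <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  if (p_flat >= alpha) {
    return(structure(list(class = "flat", chi2_flat = chi2, p_flat = p_flat,
                          p_peak = NA_real_),
                     class = "ild_tuning_class"))
  }
  # peak test: interior level higher than both extremes
  v <- phi * pmax(mean_counts, mbar) / n_trials
  interior <- 2:(k - 1)
  p_peak <- vapply(interior, function(i) {
    z_lo <- (mean_counts[i] - mean_counts[1]) / sqrt(v[i] + v[1])
    z_hi <- (mean_counts[i] - mean_counts[k]) / sqrt(v[i] + v[k])
    max(stats::pnorm(z_lo, lower.tail = FALSE),
        stats::pnorm(z_hi, lower.tail = FALSE))
  }, numeric(1))
  p_adj <- min(p_peak) * length(interior) # Bonferroni
  cls <- if (p_adj < alpha) "peaked" else "monotonic"
  structure(list(class = cls, chi2_flat = chi2, p_flat = p_flat,
                 p_peak = p_adj),
            class = "ild_tuning_class")
}
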