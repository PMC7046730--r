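#' Topographic-map recovery analysis on a simulated population
#'
#' Runs the full estimation chain on one simulated dataset: draw
#' trial-by-trial counts for every neuron on the (original) stimulus
#' grid, fit each neuron's Kent receptive field with the plug-in
#' overdispersion pooled from its own counts, keep neurons with a
#' significant RF, fitted elevation below `elevation_max` and a positive
#' anteroposterior position, and fit the azimuth-vs-position line with
#' the systematic error added in quadrature.
#'
#' @param population a [make_population()].
#' @param grid the stimulus [hrir_grid()].
#' @param n_trials trials per direction.
#' @param seed integer seed.
#' @param systematic_error degrees, added in quadrature to each fitted
#'   azimuth's statistical error (default 19).
#' @param elevation_max keep neurons with fitted elevation below this
#'   (degrees; avoids the region where the two coordinate frames
#'   diverge).
#' @return list with `map` (a [fit_topographic_map()] result), `fits`
#'   (per-neuron rf_fit list), `table` (per-neuron data.frame with fitted
#'   and true azimuths, errors, inclusion flags).
#' @export
map_recovery_analysis <- function(population, grid, n_trials = 30, seed = 1,
                                  systematic_error = 19, elevation_max = 30) {
  sim <- simulate_population_counts(population, grid, n_trials, seed)
  nn <- length(population$neurons)
  fits <- vector("list", nn)
  tab <- data.frame(neuron = seq_len(nn),
                    ap_position = population$truth$ap_position,
                    true_azimuth = population$truth$azimuth,
                    fitted_azimuth = NA_real_, fitted_elevation = NA_real_,
                    azimuth_error = NA_real_, significant = FALSE,
                    included = FALSE)
  for (i in seq_len(nn)) {
    counts <- t(sim$counts[i, , ])
    phi_i <- tryCatch(pooled_overdispersion(counts), error = function(e) 1)
    fit <- fit_kent(counts, sim$directions, phi = phi_i, frame = grid$frame)
    fits[[i]] <- fit
    if (isTRUE(fit$converged)) {
      tab$fitted_azimuth[i] <- fit$center$frontz["azimuth"]
      tab$fitted_elevation[i] <- fit$center$frontz["elevation"]
      tab$azimuth_error[i] <- fit$errors["azimuth"]
      tab$significant[i] <- fit$significant
    }
  }
  tab$included <- tab$significant &
    is.finite(tab$fitted_azimuth) & is.finite(tab$azimuth_error) &
    tab$fitted_elevation < elevation_max & tab$ap_position > 0
  inc <- tab[tab$included, ]
  map <- fit_topographic_map(inc$ap_position, inc$fitted_azimuth,
                             inc$azimuth_error, systematic_error)
  list(map = map, fits = fits, table = tab)
}

#' Cue-freezing similarity analysis on a simulated population
#'
#' Simulates responses of a population to the original stimulus grid and
#' to any set of cue-frozen variants (plus an independent control run of
#' the original), computes per-neuron cosine similarity indices between
#' the original and each condition, applies the reproducibility filter
#' to the control SI, and reports normalized similarity (NSI) losses.
#'
#' @param population a [make_population()].
#' @param grid the original [hrir_grid()].
#' @param conditions named list of cue-frozen grids (e.g.
#'   `list(frozen_itd = freeze_itd(g), ...)`); a `control` condition
#'   (identical grid, independent noise) is always added.
#' @param n_trials trials per direction (default 20, as in cue-freezing
#'   protocols that interleave many conditions).
#' @param seed integer seed.
#' @param alpha reproducibility-filter level.
#' @return data.frame, one row per neuron: `true_azimuth`, `si_control`,
#'   `si_control_error`, `reproducible`, and per condition `si_<name>`
#'   and `nsi_loss_<name>`.
#' @export
cue_freezing_analysis <- function(population, grid, conditions,
                                  n_trials = 20, seed = 1, alpha = 0.01) {
  stopifnot(length(names(conditions)) == length(conditions))
  runs <- c(list(original = grid, control = grid), conditions)
  sims <- lapply(seq_along(runs), function(j) {
    simulate_population_counts(population, runs[[j]], n_trials,
                               seed = derive_seed(seed, 101L, j))
  })
  names(sims) <- names(runs)
  nn <- length(population$neurons)
  out <- data.frame(neuron = seq_len(nn),
                    true_azimuth = population$truth$azimuth)
  si_of <- function(sim_a, sim_b, i) {
    a <- rowSums(sim_a$counts[i, , ]) # per-direction counts over trials
    b <- rowSums(sim_b$counts[i, , ])
    tryCatch(cosine_si(a, b), error = function(e) list(si = NA_real_,
                                                       si_error = NA_real_))
  }
  ctrl <- lapply(seq_len(nn), function(i) si_of(sims$original, sims$control, i))
  out$si_control <- vapply(ctrl, `[[`, numeric(1), "si")
  out$si_control_error <- vapply(ctrl, `[[`, numeric(1), "si_error")
  out$reproducible <- is.finite(out$si_control) &
    is.finite(out$si_control_error) & out$si_control_error > 0 &
    reproducibility_filter(pmax(out$si_control, -1),
                           pmax(out$si_control_error, 1e-12), alpha)
  for (nm in names(conditions)) {
    si <- vapply(seq_len(nn), function(i) {
      si_of(sims$original, sims[[nm]], i)$si
    }, numeric(1))
    out[[paste0("si_", nm)]] <- si
    loss <- rep(NA_real_, nn)
    ok <- out$reproducible & out$si_control > 0 & is.finite(si)
    loss[ok] <- nsi_loss(si[ok], out$si_control[ok])
    out[[paste0("nsi_loss_", nm)]] <- loss
  }
  out
}
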