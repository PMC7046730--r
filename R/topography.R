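#' Topographic-map line fit with systematic errors
#'
#' Weighted least-squares (chi-square) fit of receptive-field azimuth
#' against anatomical position, with each point's error the quadrature
#' combination of its statistical (fit-derived) error and a common
#' systematic error. The systematic term models effects the statistical
#' errors cannot see (eye and pinna movement, head-filter variability
#' between animals); with it, a well-calibrated fit has chi-square per
#' degree of freedom near 1.
#'
#' @param positions anatomical positions, mm.
#' @param azimuths fitted RF azimuths, degrees.
#' @param stat_errors per-point statistical errors, degrees.
#' @param systematic_error common systematic error added in quadrature,
#'   degrees (default 19).
#' @return object of class `"map_fit"`: list with `slope` (deg/mm),
#'   `offset` (deg), `slope_error`, `offset_error`, `chi2`, `dof`,
#'   `chi2_per_dof`, `pearson_r`, `n`.
#' @export
fit_topographic_map <- function(positions, azimuths, stat_errors,
                                systematic_error = 19) {
  n <- length(positions)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (length(azimuths) != n || length(stat_errors) != n) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (stats::sd(positions) == 0) {
    stop("positions are degenerate (all identical)", call. = FALSE)
  }
  sig2 <- stat_errors^2 + systematic_error^2
  w <- 1 / sig2
  S <- sum(w); Sx <- sum(w * positions); Sy <- sum(w * azimuths)
  Sxx <- sum(w * positions^2); Sxy <- sum(w * positions * azimuths)
  delta <- S * Sxx - Sx^2
  slope <- (S * Sxy - Sx * Sy) / delta
  offset <- (Sxx * Sy - Sx * Sxy) / delta
  resid <- azimuths - (offset + slope * positions)
  chi2 <- sum(resid^2 / sig2)
  dof <- n - 2
  structure(list(slope = slope, offset = offset,
                 slope_error = sqrt(S / delta),
                 offset_error = sqrt(Sxx / delta),
                 chi2 = chi2, dof = dof, chi2_per_dof = chi2 / dof,
                 pearson_r = stats::cor(positions, azimuths),
                 systematic_error = systematic_error, n = n),
            class = "map_fit")
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf(
    "<map_fit> slope %.1f +- %.1f deg/mm, offset %.1f +- %.1f deg, chi2/dof %.2f, r %.2f (n = %d)\n",
    x$slope, x$slope_error, x$offset, x$offset_error, x$chi2_per_dof,
    x$pearson_r, x$n))
  invisible(x)
}

#' Anteroposterior positions from visual receptive-field extrapolation
#'
#' The anatomical origin of the anteroposterior (A-P) axis is defined
#' functionally: visual receptive-field azimuths measured on each probe
#' shank (superficial layers) are regressed on shank position, and the
#' extrapolated position where the visual azimuth crosses 0 degrees
#' becomes A-P zero. Neuron positions are then expressed relative to that
#' origin; downstream analyses keep only neurons with positive A-P
#' position (inside the mapped structure).
#'
#' @param shank_positions probe-shank positions, mm (>= 2 distinct).
#' @param visual_rf_azimuths multi-unit visual RF azimuths per shank,
#'   degrees.
#' @param neuron_positions positions to re-reference, mm (defaults to the
#'   shank positions).
#' @return list with `origin` (mm), `slope` (deg/mm), and `positions`
#'   (re-referenced neuron positions, mm).
#' @export
estimate_ap_positions <- function(shank_positions, visual_rf_azimuths,
                                  neuron_positions = shank_positions) {
  if (length(shank_positions) < 2 ||
      length(visual_rf_azimuths) != length(shank_positions)) {
    stop("need >= 2 shanks with one visual azimuth each", call. = FALSE)
  }
  if (stats::sd(shank_positions) == 0 || stats::sd(visual_rf_azimuths) == 0) {
    stop("visual-azimuth fit is degenerate", call. = FALSE)
  }
  fit <- stats::lm(visual_rf_azimuths ~ shank_positions)
  slope <- stats::coef(fit)[[2]]
  if (!is.finite(slope) || slope == 0) {
    stop("visual-azimuth fit is degenerate", call. = FALSE)
  }
  origin <- -stats::coef(fit)[[1]] / slope
  list(origin = origin, slope = slope,
       positions = neuron_positions - origin)
}
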