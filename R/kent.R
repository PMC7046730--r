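#' Kent (Fisher-Bingham 5-parameter) distribution parameters
#'
#' The Kent distribution is a localized, possibly elliptical density on
#' the sphere, used here as the receptive-field (RF) shape model because
#' auditory RFs span angular ranges where the curvature of directional
#' space matters. It is parameterized by a concentration `kappa` (> 0,
#' larger = smaller RF), an ellipticity `beta` (0 <= 2 beta < kappa; the
#' fits restrict further to 4 beta < kappa for stability), and an
#' orthonormal triple: `gamma1` the center, `gamma2`/`gamma3` the
#' major/minor axes. Here the triple is built from the center direction
#' (top-Z frame, which has no midline azimuth discontinuity) and an axis
#' orientation `psi`.
#'
#' @param azimuth,elevation RF center in top-Z degrees.
#' @param psi major-axis orientation, radians.
#' @param kappa concentration (> 0).
#' @param beta ellipticity (0 <= 2*beta < kappa).
#' @return object of class `"kent_params"`: list with `kappa`, `beta`,
#'   and 3 x 3 matrix `gammas` (columns gamma1..3), plus the generating
#'   angles.
#' @export
kent_params <- function(azimuth, elevation, psi = 0, kappa = 10, beta = 0) {
  if (kappa <= 0) stop("`kappa` must be > 0", call. = FALSE)
  if (beta < 0 || 2 * beta >= kappa) {
    stop("`beta` must satisfy 0 <= 2*beta < kappa", call. = FALSE)
  }
  az <- deg2rad(azimuth)
  el <- deg2rad(elevation)
  g1 <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  e_az <- c(-sin(az), cos(az), 0)
  e_el <- c(-sin(el) * cos(az), -sin(el) * sin(az), cos(el))
  g2 <- cos(psi) * e_az + sin(psi) * e_el
  g3 <- cross3(g1, g2)
  structure(list(kappa = kappa, beta = beta,
                 gammas = cbind(g1, g2, g3),
                 azimuth = azimuth, elevation = elevation, psi = psi),
            class = "kent_params")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Kent density, normalized to 1 at the center
#'
#' `exp(kappa * (gamma1 . x - 1) + beta * ((gamma2 . x)^2 - (gamma3 . x)^2))`:
#' equal to 1 at `x = gamma1`, and for negligible `beta` equal to
#' `exp(-1/2)` on the circle where `x . gamma1 = 1 - 1/(2 kappa)` -- the
#' contour that defines the RF radius ([radius_from_kappa()]). At large
#' `kappa` the shape approaches a two-dimensional Gaussian.
#'
#' @param x unit vector(s): length-3 vector or n x 3 matrix.
#' @param params a [kent_params()].
#' @return density value(s) in (0, 1].
#' @export
kent_density <- function(x, params) {
  stopifnot(inherits(params, "kent_params"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(abs(sqrt(rowSums(x^2)) - 1) > 1e-6)) {
    stop("`x` must be unit vectors", call. = FALSE)
  }
  G <- params$gammas
  d1 <- x %*% G[, 1]
  d2 <- x %*% G[, 2]
  d3 <- x %*% G[, 3]
  as.numeric(exp(params$kappa * (d1 - 1) + params$beta * (d2^2 - d3^2)))
}

#' Receptive-field radius from the Kent concentration
#'
#' `rho = acos(1 - 1/(2 kappa))` degrees: the angular distance at which
#' the (beta = 0) Kent density falls to `exp(-1/2)` of its peak, the
#' spherical analogue of a Gaussian sigma. For `kappa < 0.5` the contour
#' does not exist and the radius is clipped at 90 degrees (flagged with
#' attribute `clipped`).
#'
#' @param kappa concentration (> 0), vectorized.
#' @return radius in degrees.
#' @export
radius_from_kappa <- function(kappa) {
  if (any(kappa <= 0)) stop("`kappa` must be > 0", call. = FALSE)
  arg <- 1 - 1 / (2 * kappa)
  rho <- rad2deg(acos(pmax(arg, -1)))
  clipped <- kappa < 0.5
  rho[clipped] <- 90
  if (any(clipped)) attr(rho, "clipped") <- clipped
  rho
}

# Negative quasi-log-likelihood of a baseline + amplitude * Kent rate
# model for overdispersed counts (negative-binomial with plug-in phi).
kent_negloglik <- function(theta, counts, X, phi) {
  p <- kent_params(theta[1], theta[2], theta[3],
                   kappa = exp(theta[4]),
                   beta = exp(theta[4]) / 4 * stats::plogis(theta[5]) * 0.999)
  mu_dir <- exp(theta[6]) + exp(theta[7]) * kent_density(X, p)
  mu <- rep(mu_dir, each = nrow(counts))
  -count_loglik(as.numeric(counts), mu, phi)
}

count_loglik <- function(x, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi <= 1 + 1e-12) {
    sum(stats::dpois(x, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(x, size = mu / (phi - 1), mu = mu, log = TRUE))
  }
}

#' Maximum-quasi-likelihood Kent fit of a directional response
#'
#' Fits the rate model `baseline + amplitude * Kent(direction)` to
#' trial x direction spike counts by maximizing a quasi-likelihood
#' (negative-binomial with the plug-in overdispersion `phi`; exact
#' Poisson at `phi = 1`), with the constraints `kappa > 0` and
#' `4 beta < kappa` enforced by smooth reparameterization
#' (`kappa = exp(u)`, `beta = kappa/4 * logistic(v)`). Fitting is done in
#' the top-Z frame (no midline discontinuity); the center is bounded to
#' azimuth +-144 and elevation 0-90 degrees.
#'
#' Initialization is multi-start from the highest-mean directions (ties
#' broken by lowest direction index). Parameter errors come from the
#' numerically evaluated Hessian of the negative quasi-log-likelihood at
#' the optimum. The RF is `significant` when the Kent model's BIC
#' (`-2 logL + k log n`, `k = 7`, `n` = direction x trial observations)
#' beats that of a flat direction-independent rate (`k = 1`).
#'
#' @param responses trial x direction count matrix ([window_counts()]).
#' @param directions data.frame `azimuth`, `elevation` (degrees) for the
#'   columns of `responses`.
#' @param phi plug-in overdispersion (>= 1).
#' @param frame frame of `directions` (default front-Z, the stimulus
#'   frame).
#' @param n_starts number of multi-start initializations (1-5).
#' @return object of class `"rf_fit"`: list with `params`
#'   ([kent_params()]), `center` (top-Z and front-Z azimuth/elevation,
#'   degrees), `errors` (Hessian-based, for azimuth/elevation/log-kappa),
#'   `baseline`, `amplitude`, `kappa`, `beta`, `radius`, `loglik`,
#'   `bic_kent`, `bic_flat`, `significant`, `phi`, `converged`.
#' @export
fit_kent <- function(responses, directions, phi = 1,
                     frame = c("front-z", "top-z"), n_starts = 3) {
  frame <- match.arg(frame)
  responses <- as.matrix(responses)
  if (nrow(responses) < 2) stop("need >= 2 trials per direction", call. = FALSE)
  if (length(unique(directions$elevation)) < 2) {
    stop("directions must span at least 2 elevations", call. = FALSE)
  }
  phi <- max(1, phi)
  X <- direction_to_unit(directions$azimuth, directions$elevation, frame)
  n_obs <- length(responses)
  mean_counts <- colMeans(responses)

  # flat (direction-independent) reference model
  nll_flat <- function(mu) -count_loglik(as.numeric(responses),
                                         rep(mu, n_obs), phi)
  opt_flat <- stats::optimize(nll_flat, c(1e-6, max(mean(responses), 1e-5) * 3))
  bic_flat <- 2 * opt_flat$objective + 1 * log(n_obs)

  ord <- order(-mean_counts, seq_along(mean_counts)) # ties: lowest index
  starts <- ord[seq_len(min(n_starts, length(ord)))]
  b0 <- max(min(mean_counts), 1e-3)
  a0 <- max(max(mean_counts) - b0, 1e-2)
  lower <- c(-144, 0, -pi, log(0.2), -15, log(1e-4), log(1e-4))
  upper <- c(144, 90, pi, log(500), 15, log(1e3), log(1e3))

  best <- NULL
  for (s in starts) {
    ctr <- unit_to_direction(X[s, ], "top-z")
    th0 <- c(clamp(ctr$azimuth, -143, 143), clamp(ctr$elevation, 1, 89),
             0, log(5), -1, log(b0), log(a0))
    fit <- tryCatch(
      stats::optim(th0, kent_negloglik, counts = responses, X = X, phi = phi,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE, significant = FALSE),
                     class = "rf_fit"))
  }
  th <- best$par
  H <- tryCatch(stats::optimHess(th, kent_negloglik, counts = responses,
                                 X = X, phi = phi),
                error = function(e) NULL)
  errors <- rep(NA_real_, 3)
  names(errors) <- c("azimuth", "elevation", "log_kappa")
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      v <- diag(cov)[c(1, 2, 4)]
      errors[] <- ifelse(v > 0, sqrt(pmax(v, 0)), NA_real_)
    }
  }
  kappa <- exp(th[4])
  beta <- kappa / 4 * stats::plogis(th[5]) * 0.999
  params <- kent_params(th[1], th[2], th[3], kappa, beta)
  ctr_front <- unit_to_direction(params$gammas[, 1], "front-z")
  bic_kent <- 2 * best$value + 7 * log(n_obs)
  structure(list(
    params = params,
    center = list(topz = c(azimuth = th[1], elevation = th[2]),
                  frontz = c(azimuth = ctr_front$azimuth,
                             elevation = ctr_front$elevation)),
    errors = errors,
    baseline = exp(th[6]), amplitude = exp(th[7]),
    kappa = kappa, beta = beta,
    radius = radius_from_kappa(kappa),
    loglik = -best$value, bic_kent = bic_kent, bic_flat = bic_flat,
    significant = bic_kent < bic_flat,
    flat_rate = opt_flat$minimum,
    phi = phi, n_obs = n_obs,
    converged = best$convergence == 0),
    class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<rf_fit> failed to converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<rf_fit> center (front-Z) az %.1f, el %.1f deg; kappa %.2f (radius %.1f deg); %s\n",
    x$center$frontz["azimuth"], x$center$frontz["elevation"], x$kappa,
    x$radius, if (x$significant) "significant RF" else "no significant RF"))
  invisible(x)
}
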