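test_that("Kent density identities hold exactly", {
  p <- kent_params(40, 20, psi = 0.4, kappa = 8, beta = 1.5)
  g1 <- p$gammas[, 1]
  expect_equal(kent_density(g1, p), 1)
  expect_equal(kent_density(-g1, p), exp(-2 * p$kappa))
  # gamma triple is orthonormal
  expect_equal(crossprod(p$gammas), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # exp(-1/2) contour at the defined radius when beta is negligible
  p0 <- kent_params(40, 20, kappa = 8, beta = 0)
  rho <- radius_from_kappa(8)
  x <- cos(pi / 180 * rho) * p0$gammas[, 1] + sin(pi / 180 * rho) * p0$gammas[, 2]
  expect_equal(kent_density(x / sqrt(sum(x^2)), p0), exp(-0.5))
  # sign flip of the major/minor axes leaves the density unchanged
  pflip <- p
  pflip$gammas[, 2:3] <- -pflip$gammas[, 2:3]
  set.seed(3)
  xs <- matrix(stats::rnorm(300), 100, 3)
  xs <- xs / sqrt(rowSums(xs^2))
  expect_equal(kent_density(xs, pflip), kent_density(xs, p))
  expect_error(kent_density(c(1, 1, 0), p), "unit")
  expect_error(kent_params(0, 0, kappa = 4, beta = 3), "beta")
})

test_that("the radius-concentration relation matches its closed form", {
  expect_equal(radius_from_kappa(0.5), 90)
  expect_equal(radius_from_kappa(2), acos(0.75) * 180 / pi) # 41.41 deg
  expect_equal(round(radius_from_kappa(2), 2), 41.41)
  ks <- c(0.6, 1, 2, 5, 20, 100, 1000)
  expect_true(all(diff(radius_from_kappa(ks)) < 0))
  expect_lt(radius_from_kappa(1e6), 0.06) # ~ sqrt(1/kappa) radians
  expect_equal(radius_from_kappa(0.2), 90, ignore_attr = TRUE) # clipped
  expect_error(radius_from_kappa(0), "> 0")
})

test_that("large-kappa Kent approaches the flat-space Gaussian", {
  kappa <- 100
  p <- kent_params(0, 0, kappa = kappa, beta = 0)
  rho_rad <- pi / 180 * radius_from_kappa(kappa)
  for (d in seq(0.1, 1, length.out = 5) * rho_rad) {
    x <- c(cos(d), sin(d), 0)
    gauss <- exp(-kappa * d^2 / 2)
    expect_lt(abs(kent_density(x, p) / gauss - 1), 0.01)
  }
})

test_that("Kent fits recover synthetic ground truth and reject flat data", {
  dirs <- fixture_cues$directions
  X <- direction_to_unit(dirs$azimuth, dirs$elevation, "front-z")
  truth <- kent_params(55, 15, psi = 0, kappa = 6, beta = 0.5)
  lam <- 0.1 + 2.2 * kent_density(X, truth)
  phi <- 5
  set.seed(21)
  counts <- t(replicate(30, stats::rnbinom(length(lam),
                                           size = lam / (phi - 1), mu = lam)))
  f <- fit_kent(counts, dirs, phi = phi, frame = "front-z")
  expect_true(f$converged)
  expect_true(f$significant)
  expect_lt(abs(f$center$frontz["azimuth"] - 55),
            3 * max(f$errors["azimuth"], 2))
  expect_lt(abs(f$center$frontz["elevation"] - 15), 10)
  expect_gt(f$kappa, 3)
  expect_lt(f$kappa, 12)
  # flat rates: flat model preferred
  set.seed(22)
  flat_counts <- matrix(stats::rpois(30 * nrow(dirs), 0.8), 30)
  f0 <- fit_kent(flat_counts, dirs, phi = 1, frame = "front-z")
  expect_false(f0$significant)
  expect_lt(f0$bic_flat, f0$bic_kent)
  expect_error(fit_kent(counts[1, , drop = FALSE], dirs, 1), "2 trials")
})

test_that("center errors shrink roughly as one over sqrt trials", {
  dirs <- fixture_cues$directions
  X <- direction_to_unit(dirs$azimuth, dirs$elevation, "front-z")
  truth <- kent_params(40, 10, kappa = 6)
  lam <- 0.1 + 2 * kent_density(X, truth)
  set.seed(30)
  c60 <- t(replicate(60, stats::rpois(length(lam), lam)))
  f30 <- fit_kent(c60[1:30, ], dirs, phi = 1)
  f60 <- fit_kent(c60, dirs, phi = 1)
  ratio <- f60$errors["azimuth"] / f30$errors["azimuth"]
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 0.9) # ~ 1/sqrt(2) = 0.71
})

test_that("fitted parameters are invariant to a rigid rotation of directions", {
  dirs <- fixture_cues$directions
  X <- direction_to_unit(dirs$azimuth, dirs$elevation, "front-z")
  truth <- kent_params(30, 20, kappa = 7)
  lam <- 0.15 + 2 * kent_density(X, truth)
  set.seed(33)
  counts <- t(replicate(40, stats::rpois(length(lam), lam)))
  f1 <- fit_kent(counts, dirs, phi = 1, frame = "front-z")
  # rotate every direction by +25 degrees of top-Z azimuth about the
  # dorsal axis; the fitted center must rotate with them
  rot <- 25
  R <- rbind(c(cos(pi / 180 * rot), -sin(pi / 180 * rot), 0),
             c(sin(pi / 180 * rot), cos(pi / 180 * rot), 0),
             c(0, 0, 1))
  d2 <- unit_to_direction(t(R %*% t(X)), "front-z")
  f2 <- fit_kent(counts, d2, phi = 1, frame = "front-z")
  expect_equal(f2$center$topz[["azimuth"]] - f1$center$topz[["azimuth"]],
               rot, tolerance = 1.5)
  expect_equal(f2$kappa, f1$kappa, tolerance = 0.15 * f1$kappa)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1)
})

test_that("weighted map fits handle exact and scattered data", {
  # noiseless collinear points
  x <- c(0.2, 0.8, 1.3, 1.9)
  y <- 14 + 58 * x
  m <- fit_topographic_map(x, y, stat_errors = rep(3, 4),
                           systematic_error = 0)
  expect_equal(m$slope, 58, tolerance = 1e-9)
  expect_equal(m$offset, 14, tolerance = 1e-9)
  expect_equal(m$chi2, 0, tolerance = 1e-12)
  expect_equal(m$pearson_r, 1)
  # scattered data: omitting the systematic error inflates chi2
  set.seed(40)
  n <- 80
  xs <- stats::runif(n, 0, 1.6)
  ys <- 14 + 58 * xs + stats::rnorm(n, 0, 19)
  serr <- rep(3, n)
  with_sys <- fit_topographic_map(xs, ys, serr, systematic_error = 19)
  without <- fit_topographic_map(xs, ys, serr, systematic_error = 0)
  expect_gt(without$chi2_per_dof, 5)
  expect_gt(with_sys$chi2_per_dof, 0.5)
  expect_lt(with_sys$chi2_per_dof, 1.5)
  expect_lt(abs(with_sys$slope - 58), 2 * with_sys$slope_error)
  expect_error(fit_topographic_map(rep(1, 4), y, serr[1:4]), "degenerate")
  expect_error(fit_topographic_map(x[1:2], y[1:2], serr[1:2]), "3 points")
})

test_that("anteroposterior origin is set by the visual-azimuth zero crossing", {
  r <- estimate_ap_positions(c(0, 0.4), c(-10, 10))
  expect_equal(r$origin, 0.2)
  expect_equal(r$positions, c(-0.2, 0.2))
  # exact recovery of a known origin with noiseless multi-shank input
  shanks <- c(0, 0.4, 0.8, 1.2)
  vis <- 73 * (shanks - 0.35)
  r2 <- estimate_ap_positions(shanks, vis, neuron_positions = c(0.5, 1.0))
  expect_equal(r2$origin, 0.35, tolerance = 1e-12)
  expect_equal(r2$positions, c(0.15, 0.65), tolerance = 1e-12)
  expect_error(estimate_ap_positions(c(0, 0.4), c(5, 5)), "degenerate")
})
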