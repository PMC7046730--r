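test_that("PSTHs bin trial-aligned spikes correctly", {
  events <- seq(2, 60, by = 2)
  spikes <- sort(events + 0.007)
  p <- build_psth(spikes, events, bin_width = 0.005, window = c(-0.05, 0.1))
  expect_equal(sum(p$counts > 0), 1)
  expect_equal(p$bin_centers[which.max(p$counts)], 0.0075)
  expect_equal(max(p$rate), length(events) / (length(events) * 0.005))
  expect_error(build_psth(spikes, numeric(0)), "event")
  # uniform spikes -> flat within Poisson fluctuation
  set.seed(1)
  spk <- sort(stats::runif(6000, 0, 62))
  p2 <- build_psth(spk, events)
  lam <- mean(p2$counts)
  expect_lt(max(abs(p2$counts - lam)), 5 * sqrt(lam))
})

test_that("latency-kernel simulations put the PSTH peak near the kernel peak", {
  n <- fixture_neuron(30, 5, gain = 400, overdispersion = 1,
                      latency_peak = 0.012)
  pop <- structure(list(neurons = list(n),
                        truth = data.frame(neuron = 1, azimuth = 30)),
                   class = "synthetic_population")
  rec <- simulate_recording(pop, fixture_grid, n_trials = 20, seed = 10)
  p <- build_psth(rec$spikes$time_s, rec$events$time_s, bin_width = 0.005,
                  window = c(0, 0.03))
  expect_gte(p$peak_latency, 0.010)
  expect_lt(p$peak_latency, 0.015)
  # mean latency matches the truncated-kernel oracle
  rel <- unlist(lapply(rec$events$time_s, function(e) {
    s <- rec$spikes$time_s - e
    s[s >= 0.005 & s < 0.020]
  }))
  tt <- seq(0.005, 0.020, length.out = 2000)
  dens <- (tt / 0.012) * exp(1 - tt / 0.012)
  oracle_mean <- sum(tt * dens) / sum(dens)
  expect_equal(mean(rel), oracle_mean, tolerance = 0.03)
})

test_that("window counts use a half-open onset-aligned window", {
  events <- data.frame(time_s = c(1, 3, 5, 7), direction = c(1, 2, 1, 2))
  spikes <- c(1.005, 1.020, 3.0199, 5.010, 5.012)
  m <- window_counts(spikes, events)
  expect_equal(as.integer(m), c(1L, 2L, 1L, 0L)) # trial-major by direction
  expect_equal(dim(m), c(2L, 2L))
  # 20.0 ms excluded, 5.0 ms included
  expect_equal(sum(window_counts(c(1.020), events)), 0)
  expect_equal(sum(window_counts(c(1.005), events)), 1)
  expect_error(window_counts(spikes, data.frame(time_s = c(1, 1.01),
                                                direction = 1:2)),
               "spacing")
})

test_that("overdispersion estimates recover the generating phi", {
  expect_equal(estimate_overdispersion(rep(4, 50)), 0)
  set.seed(2)
  x <- stats::rpois(10000, 6)
  expect_lt(abs(estimate_overdispersion(x) - 1), 3 * sqrt(2 / length(x)))
  phi_true <- 5.6
  mu <- 6
  y <- stats::rnbinom(10000, size = mu / (phi_true - 1), mu = mu)
  expect_lt(abs(estimate_overdispersion(y) - phi_true) / phi_true, 0.1)
  expect_error(estimate_overdispersion(rep(0, 10)), "zero mean")
  # pooled version on a matrix with direction-dependent means
  m <- sapply(c(2, 5, 9), function(l)
    stats::rnbinom(4000, size = l / (phi_true - 1), mu = l))
  expect_lt(abs(pooled_overdispersion(m) - phi_true) / phi_true, 0.1)
})

test_that("the quasi-Poisson tail matches exact Poisson and Monte Carlo", {
  r <- quasi_poisson_test(10, 2, phi = 1)
  expect_equal(r$p_value, 1 - stats::ppois(10, 2))
  expect_true(r$is_significant)
  # N = 0 is never significant
  expect_gte(quasi_poisson_test(0, 2, phi = 3)$p_value, 0.6)
  # overdispersed tail vs a large sampling oracle
  set.seed(8)
  phi <- 4; m <- 6; N <- 25
  draws <- stats::rnbinom(4e5, size = m / (phi - 1), mu = m)
  p_mc <- mean(draws > N)
  p <- quasi_poisson_test(N, m, phi)$p_value
  expect_lt(abs(p - p_mc), 4 * sqrt(p_mc * (1 - p_mc) / 4e5))
  expect_message(quasi_poisson_test(3, 1, phi = 0.5), "clamped")
  expect_error(quasi_poisson_test(-1, 2), "nonnegative")
})

test_that("false-positive rate stays at the nominal level across phi", {
  set.seed(12)
  m <- 8
  for (phi in c(1, 3, 6)) {
    draws <- if (phi == 1) stats::rpois(20000, m)
             else stats::rnbinom(20000, size = m / (phi - 1), mu = m)
    pv <- if (phi == 1) 1 - stats::ppois(draws, m)
          else 1 - stats::pnbinom(draws, size = m / (phi - 1), mu = m)
    # discrete CDF makes the test conservative; allow 2x + binomial noise
    expect_lte(mean(pv < 0.001), 0.002 + 3 * sqrt(0.001 / 20000))
  }
})

test_that("binomial fraction errors reproduce published precision", {
  r <- binomial_fraction_se(2016, 3556)
  expect_equal(round(r$fraction_pct, 1), 56.7)
  expect_equal(round(r$se_pct, 1), 0.8)
  r2 <- binomial_fraction_se(97, 592)
  expect_equal(round(r2$fraction_pct, 1), 16.4)
  expect_equal(round(r2$se_pct, 1), 1.5)
  r3 <- binomial_fraction_se(0, 100)
  expect_equal(r3$fraction_pct, 0)
  expect_equal(r3$se_pct, 0)
  expect_error(binomial_fraction_se(5, 4), "k <= n")
})

test_that("response significance separates driven neurons from null ones", {
  pop <- make_population(4, seed = 3)
  sim <- simulate_population_counts(pop, fixture_grid, n_trials = 20, seed = 4)
  for (i in 1:4) {
    r <- response_significance(t(sim$counts[i, , ]), t(sim$spont[i, , ]))
    expect_true(r$is_significant)
  }
  # a null neuron: evoked distribution identical to spontaneous scaling
  set.seed(5)
  null_ev <- matrix(stats::rpois(20 * 85, 0.075), 20, 85)
  null_sp <- matrix(stats::rpois(20 * 85, 0.25), 20, 85)
  r0 <- response_significance(null_ev, null_sp)
  expect_gt(r0$p_value, 0.001)
})
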