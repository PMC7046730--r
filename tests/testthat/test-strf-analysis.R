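chord_small <- generate_random_chord(seed = 11, total_minutes = 0.5,
                                     n_repeats = 4)

test_that("the STA equals its definition on a single spike", {
  np <- nrow(chord_small$left)
  counts <- integer(np * chord_small$n_repeats)
  counts[500] <- 1L
  st <- compute_sta(counts, chord_small, min_spikes = 1)
  # at lag 1 the STA is the pattern one bin earlier, minus the stimulus mean
  expect_equal(st$sta[2, , 1], chord_small$right[499, ] - st$stim_mean[2, ])
  expect_equal(st$sta[1, , 3], chord_small$left[497, ] - st$stim_mean[1, ])
  expect_equal(st$n_spikes, 1)
})

test_that("stimulus-independent spiking gives a null STA at the 1/sqrt(n) rate", {
  np <- nrow(chord_small$left) * chord_small$n_repeats
  set.seed(12)
  counts <- stats::rpois(np, 10000 / np)
  st <- compute_sta(counts, chord_small)
  sigma <- sqrt(0.25 / st$n_spikes)
  expect_lt(max(abs(st$sta)), 5 * sigma)
  # convergence rate ~ 1/sqrt(n_spikes)
  rms <- vapply(c(400, 1600, 6400), function(n) {
    cts <- stats::rpois(np, n / np)
    sqrt(mean(compute_sta(cts, chord_small)$sta^2))
  }, numeric(1))
  expect_equal(rms[1] / rms[2], 2, tolerance = 0.4)
  expect_equal(rms[2] / rms[3], 2, tolerance = 0.4)
  # too few spikes is a refusal, not a bad estimate
  expect_error(compute_sta(integer(np), chord_small), "not analyzable")
  expect_error(compute_sta(counts[-1], chord_small), "per 10-ms")
})

test_that("significance masks have the documented Bonferroni geometry", {
  np <- nrow(chord_small$left) * chord_small$n_repeats
  set.seed(13)
  st <- sta_significance(compute_sta(stats::rpois(np, 0.3), chord_small))
  expect_equal(st$n_pixels, 960) # 2 ears x 48 tones x 10 lags
  expect_true(all(st$mask %in% c(-1L, 0L, 1L)))
  # family-wise false positives under the null: rare
  fp <- replicate(40, {
    s <- sta_significance(compute_sta(stats::rpois(np, 0.3), chord_small))
    any(s$mask != 0)
  })
  expect_lte(mean(fp), 0.05)
})

test_that("LN-model spikes light up the kernel with correct signs", {
  n <- fixture_neuron(10, 5, kappa = 6)
  r <- simulate_chord_response(n, chord_small, seed = 14)
  st <- sta_significance(compute_sta(r$counts, chord_small))
  k <- r$kernel[2, , 2] # contralateral ear, 10-20 ms lag
  strong <- order(-abs(k))[1:5]
  expect_equal(sign(st$sta[2, strong, 2]), sign(k[strong]))
  expect_gt(sum(st$mask != 0), 10)
  # flagged pixels carry the kernel's sign where the kernel is strong
  flagged <- which(st$mask[2, , 2] != 0)
  expect_true(all(sign(st$mask[2, flagged, 2]) == sign(k[flagged])))
})

test_that("the binaural similarity index tracks ear symmetry", {
  n_front <- fixture_neuron(5, 5)
  r <- simulate_chord_response(n_front, chord_small, seed = 15)
  st <- compute_sta(r$counts, chord_small)
  expect_gt(binaural_si(st), 0.3)
  # copying the contra block makes BSI exactly 1; negating it, -1
  st_sym <- st
  st_sym$sta[1, , ] <- st_sym$sta[2, , ]
  expect_equal(binaural_si(st_sym), 1)
  st_anti <- st
  st_anti$sta[1, , ] <- -st_anti$sta[2, , ]
  expect_equal(binaural_si(st_anti), -1)
  # independent random blocks: near zero
  set.seed(16)
  st_null <- st
  st_null$sta[1, , ] <- stats::rnorm(480)
  st_null$sta[2, , ] <- stats::rnorm(480)
  expect_lt(abs(binaural_si(st_null)), 4 / sqrt(479))
  # BSI decreases with RF azimuth across simulated neurons
  bsis <- vapply(c(5, 45, 110), function(az) {
    nn <- fixture_neuron(az, 5)
    rr <- simulate_chord_response(nn, chord_small, seed = 17)
    binaural_si(compute_sta(rr$counts, chord_small))
  }, numeric(1))
  expect_true(all(diff(bsis) < 0))
})

test_that("population fraction maps respect groups and normalization", {
  n1 <- fixture_neuron(10, 5)
  n2 <- fixture_neuron(100, 5)
  strfs <- lapply(list(n1, n2), function(n) {
    r <- simulate_chord_response(n, chord_small, seed = 18)
    sta_significance(compute_sta(r$counts, chord_small))
  })
  pm <- population_fraction_map(strfs, c(10, 100), split = 35)
  expect_equal(pm$frontal$n, 1)
  expect_equal(pm$lateral$n, 1)
  expect_true(all(pm$frontal$positive %in% c(0, 1)))
  expect_equal(pm$frontal$positive, (strfs[[1]]$mask == 1) * 1)
  # frontal group: positive structure concentrated in the amplified bands
  f <- chord_small$frequencies
  amp_band <- f >= 48e3 & f <= 60e3
  att_band <- f >= 63e3 & f <= 76e3
  expect_gt(mean(pm$frontal$positive[2, amp_band, 1:3]),
            mean(pm$frontal$positive[2, att_band, 1:3]))
  expect_error(population_fraction_map(strfs, c(10, 20), split = 35),
               "non-empty")
})
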