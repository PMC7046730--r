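test_that("VAS synthesis produces tapered, HRIR-filtered bursts", {
  g <- fixture_grid
  s <- synthesize_vas(0, 0, g, noise_seed = 3)
  expect_length(s$left, round(0.1 * g$sample_rate))
  expect_length(s$right, length(s$left))
  # same seed -> bit-identical; different seed -> different noise
  s2 <- synthesize_vas(0, 0, g, noise_seed = 3)
  expect_identical(s$left, s2$left)
  s3 <- synthesize_vas(0, 0, g, noise_seed = 4)
  expect_false(identical(s$left, s3$left))
  expect_error(synthesize_vas(1, 1, g, 1), "not on the grid")
})

test_that("a spectral notch in the HRIR appears in the synthesized stimulus", {
  # flat-spectrum impulse grid vs the same grid with a deep smooth notch
  # near 40 kHz; oracle = the notched IR's own measured magnitude response
  dirs <- data.frame(azimuth = 0, elevation = 0)
  flat <- impulse_grid(dirs, 100, 100, len = 512)
  fs <- flat$sample_rate
  nfft <- 2048
  f <- (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft
  gain_db <- -30 * exp(-((f - 40e3) / 4e3)^2) # smooth 30 dB notch
  half <- 10^(gain_db / 20) * exp(-2i * pi * f * 100 / fs)
  full_sp <- c(half, Conj(rev(half[2:(length(half) - 1)])))
  ir <- Re(stats::fft(full_sp, inverse = TRUE) / nfft)[1:512]
  notched <- hrir_grid(fs, dirs, matrix(ir, 1), matrix(ir, 1))

  sp <- grid_spectra(notched)
  notch_bins <- sp$frequency >= 38e3 & sp$frequency <= 42e3
  ref_bins <- sp$frequency >= 25e3 & sp$frequency <= 30e3
  ir_depth <- mean(sp$right_db[1, ref_bins]) - mean(sp$right_db[1, notch_bins])
  expect_gt(ir_depth, 20) # the design survives truncation

  pow_db <- function(x, lo, hi) {
    X <- Mod(stats::fft(x))^2
    fr <- (seq_along(X) - 1) * fs / length(X)
    10 * log10(mean(X[fr >= lo & fr <= hi]))
  }
  s_flat <- synthesize_vas(0, 0, flat, noise_seed = 9)
  s_notch <- synthesize_vas(0, 0, notched, noise_seed = 9)
  stim_depth <- (pow_db(s_flat$right, 38e3, 42e3) -
                   pow_db(s_notch$right, 38e3, 42e3)) -
    (pow_db(s_flat$right, 25e3, 30e3) - pow_db(s_notch$right, 25e3, 30e3))
  expect_equal(stim_depth, ir_depth, tolerance = 0.15 * ir_depth)
  # flat HRIR: in-band spectrum flat within a few dB after smoothing
  X <- Mod(stats::fft(s_flat$right))^2
  fr <- (seq_along(X) - 1) * fs / length(X)
  bands <- seq(10e3, 75e3, by = 5e3)
  lev <- vapply(bands, function(b)
    10 * log10(mean(X[fr >= b & fr < b + 5e3])), numeric(1))
  expect_lt(diff(range(lev)), 3)
})

test_that("each freezing operation alters exactly one cue", {
  g <- fixture_grid
  ct0 <- compute_ild(g)
  ildf0 <- attr(ct0, "ild_by_frequency")

  gi <- freeze_itd(g)
  cti <- compute_ild(gi)
  expect_equal(cti$itd_us, rep(0, nrow(cti)))
  expect_lt(max(abs(attr(cti, "ild_by_frequency") - ildf0)), 1e-9)
  expect_identical(freeze_itd(gi)$left, gi$left) # already-zero-ITD fixpoint

  gl <- freeze_ild(g)
  ctl <- compute_ild(gl)
  expect_lt(max(abs(ctl$ild_db)), 1e-9)
  expect_equal(ctl$itd_us, ct0$itd_us)
  # spectral shape (per-frequency ILD relative to broadband) preserved
  shape <- function(ct) attr(ct, "ild_by_frequency") - ct$ild_db
  expect_lt(max(abs(shape(ctl) - shape(ct0))), 1e-9)
  expect_equal(freeze_ild(gl)$left, gl$left, tolerance = 1e-12)

  gs <- freeze_spectrum(g)
  cts <- compute_ild(gs)
  expect_equal(cts$ild_db, ct0$ild_db, tolerance = 1e-6)
  expect_equal(cts$itd_us, ct0$itd_us)
  sp <- grid_spectra(gs)
  expect_lt(max(apply(sp$right_db, 1, function(x) diff(range(x)))), 1e-9)
  expect_lt(max(apply(sp$left_db, 1, function(x) diff(range(x)))), 1e-9)

  gm <- make_monaural(g)
  expect_true(all(gm$left == 0))
  expect_identical(gm$right, g$right)
  expect_true(all(compute_ild(gm)$ild_db == 120)) # capped sentinel
  s <- synthesize_vas(36, 20, gm, noise_seed = 2)
  expect_true(all(s$left == 0))
  expect_equal(s$right, synthesize_vas(36, 20, g, noise_seed = 2)$right)
})

test_that("frozen-level equalization balances a constructed imbalance", {
  dirs <- data.frame(azimuth = c(0, 90), elevation = 0)
  g <- impulse_grid(dirs, 20, 20, gain_left = 10^(6 / 20),
                    gain_right = 10^(-6 / 20))
  lev <- grid_spectra(freeze_ild(g))
  expect_equal(rowMeans(lev$left_db), rowMeans(lev$right_db), tolerance = 1e-9)
  expect_equal(rowMeans(lev$left_db), c(0, 0), tolerance = 1e-9)
  gz <- impulse_grid(dirs, 20, 20, gain_left = 0)
  expect_error(freeze_ild(gz), "silent ear")
})

test_that("the extended-ILD schedule has 41 levels x 30 repeats and exact gains", {
  set <- build_extended_ild_set(seed = 6)
  expect_equal(sort(unique(set$ild_db)), seq(-40, 40, by = 2))
  expect_true(all(table(set$ild_db) == 30))
  expect_equal(nrow(set), 41 * 30)
  # order is randomized but reproducible
  expect_identical(build_extended_ild_set(seed = 6)$ild_db, set$ild_db)
  expect_false(identical(build_extended_ild_set(seed = 7)$ild_db, set$ild_db))
  tr <- set$trial[set$ild_db == 10][1]
  s <- synthesize_ild_trial(set, tr)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(20 * log10(rms(s$right) / rms(s$left)), 10, tolerance = 0.1)
})

test_that("random chords are balanced, ear-independent, and repeatable", {
  ch <- generate_random_chord(seed = 5, total_minutes = 2, n_repeats = 20)
  expect_equal(nrow(ch$left), 12000)
  expect_equal(ncol(ch$left), 48)
  expect_equal(ch$frequencies[1], 5000)
  expect_equal(ch$frequencies[48], 5000 * 2^(47 / 12))
  n <- length(ch$left)
  # ON probability within 3 binomial sigma of 0.5
  expect_lt(abs(mean(ch$left) - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(ch$right) - 0.5), 3 * sqrt(0.25 / n))
  # ears uncorrelated (|r| < 3 sigma under independence)
  r <- stats::cor(as.numeric(ch$left), as.numeric(ch$right))
  expect_lt(abs(r), 3 / sqrt(n))
  expect_identical(generate_random_chord(5, 2, 20)$left, ch$left)
})
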