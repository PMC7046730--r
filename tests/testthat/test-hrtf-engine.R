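test_that("Golay pairs have the complementary autocorrelation property", {
  expect_equal(generate_golay_pair(1)$code_a, c(1, 1))
  expect_equal(generate_golay_pair(1)$code_b, c(1, -1))
  expect_length(generate_golay_pair(16)$code_a, 65536)
  expect_error(generate_golay_pair(-1), "non-negative")

  for (order in c(3, 6, 10)) {
    p <- generate_golay_pair(order)
    n <- 2^order
    acf_sum <- vapply(0:(n - 1), function(k) {
      sum(p$code_a[1:(n - k)] * p$code_a[(1 + k):n]) +
        sum(p$code_b[1:(n - k)] * p$code_b[(1 + k):n])
    }, numeric(1))
    expect_equal(acf_sum[1], 2 * n)
    expect_equal(acf_sum[-1], rep(0, n - 1))
  }
})

test_that("Golay reconstruction inverts convolution with the codes", {
  p <- generate_golay_pair(8)
  # identity system
  h <- reconstruct_hrir(c(p$code_a, 0), c(p$code_b, 0), p)
  expect_equal(h, c(1, 0), tolerance = 1e-12)
  # known 8-tap filter, direct-convolution oracle
  taps <- c(0.3, -1.2, 0.8, 0, 0.05, -0.4, 0.9, 0.1)
  ra <- stats::convolve(p$code_a, rev(taps), type = "open")
  rb <- stats::convolve(p$code_b, rev(taps), type = "open")
  h <- reconstruct_hrir(ra, rb, p)
  expect_length(h, 8)
  expect_lt(max(abs(h - taps)) / max(abs(taps)), 1e-9)
  # pure k-sample delay
  k <- 13
  dl <- function(code) c(numeric(k), code, numeric(4))
  h <- reconstruct_hrir(dl(p$code_a), dl(p$code_b), p)
  expect_equal(which.max(abs(h)), k + 1)
  # randomized property: arbitrary short systems are recovered exactly
  set.seed(42)
  for (rep in 1:5) {
    taps <- stats::rnorm(17)
    ra <- stats::convolve(p$code_a, rev(taps), type = "open")
    rb <- stats::convolve(p$code_b, rev(taps), type = "open")
    h <- reconstruct_hrir(ra, rb, p)
    expect_equal(h[1:17], taps, tolerance = 1e-9)
  }
  expect_error(reconstruct_hrir(1:10, 1:10, p), "as long as")
})

test_that("ITD is the right-minus-left peak-time difference", {
  imp <- function(at, len = 64) { x <- numeric(len); x[at] <- 1; x }
  expect_equal(compute_itd(imp(10), imp(10), 5e5), 0)
  expect_equal(compute_itd(imp(10), imp(25), 5e5), 30) # 15 samples at 500 kHz
  expect_equal(compute_itd(imp(10), imp(25), 5e5),
               -compute_itd(imp(25), imp(10), 5e5)) # ear-swap antisymmetry
  expect_error(compute_itd(numeric(8), imp(3, 8), 5e5), "all-zero")
})

test_that("spherical-head synthetic ITDs stay below the path-difference bound", {
  ct <- compute_ild(fixture_grid)
  d_over_c <- fixture_spec$ear_separation / fixture_spec$sound_speed # 29.15 us
  expect_lte(max(abs(ct$itd_us)), d_over_c * 1e6 + 2) # one-sample quantization
  i90 <- which(ct$azimuth == 90 & ct$elevation == 0)
  expect_equal(abs(ct$itd_us[i90]), d_over_c * 1e6, tolerance = 0.1)
  # odd in azimuth
  m <- match(paste(-ct$azimuth, ct$elevation), paste(ct$azimuth, ct$elevation))
  expect_equal(ct$itd_us, -ct$itd_us[m])
})

test_that("broadband ILD follows level ratios and flips sign on ear swap", {
  dirs <- data.frame(azimuth = c(0, 30), elevation = 0)
  g <- impulse_grid(dirs, delay_left = 20, delay_right = 20)
  ct <- compute_ild(g)
  expect_equal(ct$ild_db, c(0, 0))
  expect_equal(max(abs(attr(ct, "ild_by_frequency"))), 0)
  # right ear 10x amplitude -> +20 dB everywhere
  g2 <- impulse_grid(dirs, 20, 20, gain_left = 1, gain_right = 10)
  ct2 <- compute_ild(g2)
  expect_equal(ct2$ild_db, c(20, 20), tolerance = 1e-9)
  # ear swap flips the sign
  g3 <- g2
  tmp <- g3$left; g3$left <- g3$right; g3$right <- tmp
  expect_equal(compute_ild(g3)$ild_db, -ct2$ild_db, tolerance = 1e-12)
  # synthetic grid: ILD maximum at the construction's peak azimuth (65 deg)
  fine <- make_synthetic_hrtf(
    synthetic_hrtf_spec(azimuths = seq(-140, 140, by = 5), elevations = c(0, 20)))
  ctf <- compute_ild(fine)
  horiz <- ctf[ctf$elevation == 0, ]
  expect_equal(horiz$azimuth[which.max(horiz$ild_db)], 65)
})

test_that("hemifield mirroring swaps ears and yields an odd ITD field", {
  half_spec <- synthetic_hrtf_spec(azimuths = seq(0, 144, by = 18))
  half <- make_synthetic_hrtf(half_spec)
  full <- mirror_hemifield(half)
  i_src <- which(full$directions$azimuth == 36 & full$directions$elevation == 20)
  i_mir <- which(full$directions$azimuth == -36 & full$directions$elevation == 20)
  expect_equal(full$left[i_mir, ], full$right[i_src, ])
  expect_equal(full$right[i_mir, ], full$left[i_src, ])
  # midline unchanged by a second mirror of the midline subset
  mid <- which(full$directions$azimuth == 0)
  expect_equal(full$left[mid, ], half$left[half$directions$azimuth == 0, ])
  # ITD odd in azimuth
  ct <- compute_ild(full)
  m <- match(paste(-ct$azimuth, ct$elevation), paste(ct$azimuth, ct$elevation))
  expect_equal(ct$itd_us, -ct$itd_us[m])
  expect_error(mirror_hemifield(full), "hemifield")
  no_mid <- make_synthetic_hrtf(synthetic_hrtf_spec(azimuths = seq(18, 144, 18)))
  expect_warning(mirror_hemifield(no_mid), "midline")
})

test_that("coordinate-frame conversion is an exact involution", {
  set.seed(7)
  d <- data.frame(azimuth = stats::runif(1000, -179, 179),
                  elevation = stats::runif(1000, -89, 89))
  back <- convert_frame(convert_frame(d, "top-z", "front-z"), "front-z", "top-z")
  expect_direction_equal(back, d, tol = 1e-10)
  # horizontal plane: azimuth shared between frames
  h <- data.frame(azimuth = seq(-144, 144, 18), elevation = 0)
  expect_direction_equal(convert_frame(h, "front-z", "top-z"), h)
  # front-Z pole: elevation canonicalized to 0
  pole <- unit_to_direction(c(1, 0, 0), "front-z")
  expect_equal(pole$elevation, 0)
})
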