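# Shared fixtures, generated once per test run (never stored on disk).

fixture_spec <- synthetic_hrtf_spec()
fixture_grid <- make_synthetic_hrtf(fixture_spec)
fixture_cues <- cue_summary(fixture_grid)

# A template-matched neuron on the shared grid.
fixture_neuron <- function(azimuth, elevation = 5, kappa = 6,
                           w_spec = 1, w_ild = 0, ...) {
  synthetic_neuron(
    azimuth, elevation, kappa = kappa, w_spec = w_spec, w_ild = w_ild,
    template = neuron_template(fixture_spec, fixture_cues$frequency,
                               azimuth, elevation),
    template_frequency = fixture_cues$frequency, ...)
}

# A tiny hand-built grid: impulses with controllable delay and gain.
impulse_grid <- function(directions, delay_left, delay_right,
                         gain_left = 1, gain_right = 1,
                         sample_rate = 5e5, len = 64) {
  n <- nrow(directions)
  delay_left <- rep_len(delay_left, n)
  delay_right <- rep_len(delay_right, n)
  gain_left <- rep_len(gain_left, n)
  gain_right <- rep_len(gain_right, n)
  left <- matrix(0, n, len)
  right <- matrix(0, n, len)
  for (i in seq_len(n)) {
    left[i, delay_left[i]] <- gain_left[i]
    right[i, delay_right[i]] <- gain_right[i]
  }
  hrir_grid(sample_rate, directions, left, right)
}

expect_direction_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$azimuth, b$azimuth, tolerance = tol)
  expect_equal(a$elevation, b$elevation, tolerance = tol)
}
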