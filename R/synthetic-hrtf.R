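#' Specification for a parametric mouse-like HRTF
#'
#' Describes the synthetic head filter emulated by
#' [make_synthetic_hrtf()]: interaural time differences (ITDs) follow the
#' acoustic path-difference model for an `ear_separation` head (at the
#' defaults, at most ~29 microseconds); the broadband interaural level
#' difference (ILD) is a smooth odd function of azimuth peaking at
#' `ild_peak_azimuth`; and the spectrum carries direction-dependent
#' peaks and notches inside 5-80 kHz whose frontal pattern is a band
#' template (amplified 10-24 and 48-60 kHz, attenuated 25-45 and
#' 63-76 kHz).
#'
#' The spectral field is built from three orthonormal, zero-mean band
#' patterns weighted by the components of the direction's unit vector, so
#' the Pearson correlation between the ear spectra of two directions is a
#' (generalized) cosine of their angular separation. This gives every
#' direction a unique spectral signature that decays smoothly with
#' distance, which is what template-correlation neuron models need.
#'
#' @param ear_separation metres between the ears (default 0.01).
#' @param sound_speed metres per second (default 343).
#' @param ild_peak_azimuth degrees; azimuth of the broadband ILD maximum.
#' @param ild_max dB; broadband ILD at the peak azimuth (the per-frequency
#'   ILD excursions are larger).
#' @param notch_depth dB; peak-to-trough depth of the frontal spectral
#'   template.
#' @param bands_amplified,bands_attenuated lists of `c(lo, hi)` Hz pairs
#'   inside the analysis band.
#' @param azimuths,elevations grid of directions (front-Z frame, degrees);
#'   azimuths within +-144, elevations within 0-80.
#' @param sample_rate Hz.
#' @param ir_length impulse-response taps.
#' @param ripple_db amplitude of a seeded random fine-structure ripple
#'   shared by both ears (0 disables it; the grid is then deterministic).
#' @return list of class `"synthetic_hrtf_spec"`.
#' @export
synthetic_hrtf_spec <- function(ear_separation = 0.01, sound_speed = 343,
                                ild_peak_azimuth = 65, ild_max = 20,
                                notch_depth = 20,
                                bands_amplified = list(c(10e3, 24e3), c(48e3, 60e3)),
                                bands_attenuated = list(c(25e3, 45e3), c(63e3, 76e3)),
                                azimuths = seq(-144, 144, by = 18),
                                elevations = seq(0, 80, by = 20),
                                sample_rate = 5e5, ir_length = 512,
                                ripple_db = 0) {
  if (ild_max < 0) stop("`ild_max` must be >= 0", call. = FALSE)
  band <- c(5000, 80000)
  all_b <- c(bands_amplified, bands_attenuated)
  if (any(vapply(all_b, function(b) b[1] < band[1] || b[2] > band[2],
                 logical(1)))) {
    stop("template bands must lie inside 5-80 kHz", call. = FALSE)
  }
  if (any(azimuths < -144 - 1e-9) || any(azimuths > 144 + 1e-9) ||
      any(elevations < 0) || any(elevations > 80 + 1e-9)) {
    stop("grid must lie within azimuth +-144 and elevation 0-80 degrees",
         call. = FALSE)
  }
  structure(list(ear_separation = ear_separation, sound_speed = sound_speed,
                 ild_peak_azimuth = ild_peak_azimuth, ild_max = ild_max,
                 notch_depth = notch_depth,
                 bands_amplified = bands_amplified,
                 bands_attenuated = bands_attenuated,
                 azimuths = azimuths, elevations = elevations,
                 sample_rate = sample_rate, ir_length = ir_length,
                 band = band, ripple_db = ripple_db),
            class = "synthetic_hrtf_spec")
}

# Orthonormal zero-mean spectral component patterns on the band bins,
# each rescaled to unit peak amplitude. Component 1 is the frontal band
# template; components 2 and 3 are smooth patterns carrying the lateral
# and dorsal spectral gradients.
spectral_components <- function(spec, freq_band) {
  f <- freq_band
  raw1 <- numeric(length(f))
  for (b in spec$bands_amplified) raw1[f >= b[1] & f <= b[2]] <- 1
  for (b in spec$bands_attenuated) raw1[f >= b[1] & f <= b[2]] <- -1
  u <- (f - spec$band[1]) / diff(spec$band)
  raw <- cbind(raw1, sin(2 * pi * u), cos(2 * pi * u))
  # Gram-Schmidt with centering; equal norms make the inter-direction
  # spectral correlation an exact cosine of the angular separation
  out <- matrix(0, length(f), 3)
  for (j in 1:3) {
    v <- raw[, j] - mean(raw[, j])
    if (j > 1) {
      for (k in seq_len(j - 1)) {
        q <- out[, k]
        v <- v - sum(v * q) * q / sum(q^2)
        v <- v - mean(v)
      }
    }
    out[, j] <- v / sqrt(sum(v^2))
  }
  out / max(abs(out[, 1])) # template peak = 1 sets the dB scale
}

# Broadband ILD (dB) as a function of front-Z azimuth/elevation: odd in
# azimuth, Rayleigh-shaped with its peak at `ild_peak_azimuth`, tapering
# toward the pole with cos(elevation).
ild_profile <- function(spec, azimuth, elevation) {
  a <- azimuth / spec$ild_peak_azimuth
  spec$ild_max * a * exp((1 - a^2) / 2) * cos(deg2rad(elevation))
}

#' Generate a parametric HRIR grid with known cue structure
#'
#' Builds an [hrir_grid()] realizing a [synthetic_hrtf_spec()]: for each
#' direction, per-ear log-magnitude spectra are assembled from the
#' spectral component patterns plus half the broadband ILD per ear, the
#' interaural delay is imposed as a fractional phase delay around a common
#' base latency, and impulse responses are obtained by inverse FFT with
#' the band edges rolled off smoothly. The first and last 16 taps are
#' exactly zero (with a further cosine ramp inside), so the integer-sample
#' shifts used by ITD freezing leave magnitude spectra bit-identical.
#'
#' The left ear is the mirror (in azimuth) of the right ear, as for a
#' left-right symmetric head.
#'
#' @param spec a [synthetic_hrtf_spec()].
#' @param seed integer; only used when `spec$ripple_db > 0`.
#' @return an [hrir_grid()] in the front-Z frame.
#' @export
make_synthetic_hrtf <- function(spec = synthetic_hrtf_spec(), seed = 1) {
  stopifnot(inherits(spec, "synthetic_hrtf_spec"))
  L <- spec$ir_length
  fs <- spec$sample_rate
  nfft <- next_pow2(4L * L)
  nb <- nfft %/% 2 + 1
  freq <- (seq_len(nb) - 1) * fs / nfft
  in_band <- freq >= spec$band[1] & freq <= spec$band[2]
  comps <- spectral_components(spec, freq[in_band])
  ripple <- if (spec$ripple_db > 0) {
    with_seed(seed, stats::rnorm(sum(in_band), sd = spec$ripple_db))
  } else numeric(sum(in_band))

  dirs <- expand.grid(azimuth = spec$azimuths, elevation = spec$elevations)
  dirs <- dirs[order(dirs$elevation, dirs$azimuth), ]
  rownames(dirs) <- NULL
  n <- nrow(dirs)
  uv <- direction_to_unit(dirs$azimuth, dirs$elevation, "front-z")

  # smooth out-of-band roll-off to a -60 dB floor
  floor_amp <- 10^(-60 / 20)
  edge <- 3000
  lo_ramp <- clamp((freq - (spec$band[1] - edge)) / edge, 0, 1)
  hi_ramp <- clamp(((spec$band[2] + edge) - freq) / edge, 0, 1)
  rolloff <- 0.5 - 0.5 * cos(pi * lo_ramp * hi_ramp)

  base_delay <- 150 / fs
  d_over_c <- spec$ear_separation / spec$sound_speed
  win <- edge_window(L)

  left <- matrix(0, n, L)
  right <- matrix(0, n, L)
  for (i in seq_len(n)) {
    u <- uv[i, ]
    ild <- ild_profile(spec, dirs$azimuth[i], dirs$elevation[i])
    itd <- -d_over_c * u[2] # right minus left arrival time, seconds
    g_r <- numeric(nb)
    g_l <- numeric(nb)
    s <- spec$notch_depth / 2
    g_r[in_band] <- s * (comps %*% c(u[1], u[2], u[3])) + ild / 2 + ripple
    g_l[in_band] <- s * (comps %*% c(u[1], -u[2], u[3])) - ild / 2 + ripple
    right[i, ] <- win * design_ir(g_r, rolloff, floor_amp,
                                  base_delay + itd / 2, freq, nfft, L)
    left[i, ] <- win * design_ir(g_l, rolloff, floor_amp,
                                 base_delay - itd / 2, freq, nfft, L)
  }
  hrir_grid(fs, dirs, left, right, frame = "front-z", band = spec$band)
}

# Inverse-FFT filter design: target magnitude (dB gains in `gain_db`,
# rolled off to `floor_amp` out of band) with a pure `delay`-second linear
# phase; returns the first `L` taps.
design_ir <- function(gain_db, rolloff, floor_amp, delay, freq, nfft, L) {
  amp <- pmax(10^(gain_db / 20) * rolloff, floor_amp)
  phase <- exp(-2i * pi * freq * delay)
  half <- amp * phase
  full <- c(half, Conj(rev(half[2:(length(half) - 1)])))
  h <- Re(stats::fft(full, inverse = TRUE)) / nfft
  h[seq_len(L)]
}

# Window with the first/last `zero` taps exactly 0 and a raised-cosine
# ramp over the next `ramp` taps. Exact zero margins make integer-sample
# shifts up to `zero` taps (ITD freezing) lossless.
edge_window <- function(L, zero = 16, ramp = 16) {
  w <- rep(1, L)
  rise <- 0.5 - 0.5 * cos(pi * seq(0, 1, length.out = ramp))
  w[seq_len(zero)] <- 0
  w[zero + seq_len(ramp)] <- rise
  w[L - zero - ramp + seq_len(ramp)] <- rev(rise)
  w[L - zero + seq_len(zero)] <- 0
  w
}
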