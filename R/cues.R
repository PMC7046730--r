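#' Interaural time difference of one impulse-response pair
#'
#' The arrival time in each ear is taken as the sample index of the maximum
#' absolute value of the impulse response (no sub-sample interpolation; at a
#' 500 kHz sampling rate the 2 microsecond resolution is far below the
#' ~29 microsecond physiological maximum for a mouse-sized head). Ties are
#' broken by the earliest sample. The ITD is the right-minus-left peak time.
#'
#' @param hrir_left,hrir_right impulse-response sample vectors.
#' @param sample_rate Hz.
#' @return ITD in microseconds (positive when the right-ear peak is later).
#' @export
compute_itd <- function(hrir_left, hrir_right, sample_rate) {
  stopifnot_scalar(sample_rate)
  if (all(hrir_left == 0) || all(hrir_right == 0)) {
    stop("ITD is undefined for an all-zero impulse response", call. = FALSE)
  }
  tl <- which.max(abs(hrir_left))
  tr <- which.max(abs(hrir_right))
  (tr - tl) / sample_rate * 1e6
}

#' Localization-cue table of an HRIR grid
#'
#' Extracts, for every direction on the grid: the interaural time
#' difference (ITD, microseconds, right-minus-left peak time), the
#' broadband interaural level difference (ILD, dB, right-minus-left
#' band-average level) and the per-frequency ILD inside the analysis band.
#' Band-averaging is done on the dB magnitude spectrum (so the broadband
#' ILD is scale-equivariant and reported in the same units as the
#' per-frequency ILD).
#'
#' A silent ear yields a formally infinite ILD; values are capped at
#' `ild_cap` dB in magnitude (documented sentinel for monaural grids).
#'
#' @param grid an [hrir_grid()].
#' @param ild_cap cap (dB) on the magnitude of reported broadband ILDs.
#' @return object of class `"cue_table"`: data.frame with columns `azimuth`,
#'   `elevation`, `itd_us`, `ild_db`, plus attributes `frequency` (Hz) and
#'   `ild_by_frequency` (direction x frequency matrix, dB).
#' @export
compute_ild <- function(grid, ild_cap = 120) {
  stopifnot(inherits(grid, "hrir_grid"))
  sp <- grid_spectra(grid)
  ild_f <- sp$right_db - sp$left_db
  lev_l <- rowMeans(sp$left_db)
  lev_r <- rowMeans(sp$right_db)
  ild_bb <- clamp(lev_r - lev_l, -ild_cap, ild_cap)
  itd <- vapply(seq_len(n_directions(grid)), function(i) {
    l <- grid$left[i, ]
    r <- grid$right[i, ]
    if (all(l == 0) || all(r == 0)) NA_real_
    else compute_itd(l, r, grid$sample_rate)
  }, numeric(1))
  out <- data.frame(azimuth = grid$directions$azimuth,
                    elevation = grid$directions$elevation,
                    itd_us = itd, ild_db = ild_bb)
  attr(out, "frequency") <- sp$frequency
  attr(out, "ild_by_frequency") <- ild_f
  class(out) <- c("cue_table", "data.frame")
  out
}

#' @rdname compute_ild
#' @export
cue_table <- compute_ild

#' Mirror a lateral-hemifield HRIR grid onto the full sphere
#'
#' HRIRs are typically measured on one lateral hemifield only (stage
#' limitation); by left-right symmetry of the head, the opposite hemifield
#' is obtained by copying the transfer function of the opposite ear: for
#' the mirrored direction the left/right impulse responses are the swap of
#' the source direction's. Midline directions (azimuth 0) are kept as-is.
#'
#' @param grid an [hrir_grid()] whose azimuths are all `>= 0` (one lateral
#'   hemifield, midline included). A grid missing the midline is mirrored
#'   anyway, with a warning.
#' @return full-sphere [hrir_grid()] covering both hemifields.
#' @export
mirror_hemifield <- function(grid) {
  stopifnot(inherits(grid, "hrir_grid"))
  az <- grid$directions$azimuth
  if (any(az < 0)) {
    stop("grid must cover a single lateral hemifield (azimuth >= 0)",
         call. = FALSE)
  }
  if (!any(az == 0)) {
    warning("grid has no midline (azimuth 0) directions; mirroring anyway")
  }
  lat <- which(az > 0)
  dirs <- rbind(grid$directions,
                data.frame(azimuth = -az[lat],
                           elevation = grid$directions$elevation[lat]))
  left <- rbind(grid$left, grid$right[lat, , drop = FALSE])
  right <- rbind(grid$right, grid$left[lat, , drop = FALSE])
  hrir_grid(grid$sample_rate, dirs, left, right, grid$frame, grid$band)
}
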