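#' Head-related impulse response grid
#'
#' Container for per-direction, per-ear impulse responses on a spherical
#' grid: the physical substrate of all three sound-localization cues
#' (interaural time difference, interaural level difference, spectral
#' shape).
#'
#' @param sample_rate sampling rate in Hz (> 0).
#' @param directions data.frame with columns `azimuth`, `elevation`
#'   (degrees); each direction must appear once.
#' @param left,right numeric matrices, one row per direction, equal number
#'   of columns (impulse-response samples) for both ears.
#' @param frame coordinate frame tag of `directions` (see
#'   [direction_to_unit()]).
#' @param band analysis band in Hz; cue extraction and stimulus
#'   reproduction are restricted to this band (default 5-80 kHz).
#' @return object of class `"hrir_grid"`.
#' @export
hrir_grid <- function(sample_rate, directions, left, right,
                      frame = c("front-z", "top-z"),
                      band = c(5000, 80000)) {
  frame <- match.arg(frame)
  stopifnot_scalar(sample_rate)
  if (sample_rate <= 0) stop("`sample_rate` must be > 0", call. = FALSE)
  if (!is.data.frame(directions) ||
      !all(c("azimuth", "elevation") %in% names(directions))) {
    stop("`directions` needs `azimuth` and `elevation` columns", call. = FALSE)
  }
  left <- as.matrix(left)
  right <- as.matrix(right)
  n <- nrow(directions)
  if (nrow(left) != n || nrow(right) != n) {
    stop("one impulse-response row per direction is required", call. = FALSE)
  }
  if (ncol(left) != ncol(right)) {
    stop("left and right impulse responses must have equal length",
         call. = FALSE)
  }
  key <- paste(signif(directions$azimuth, 10), signif(directions$elevation, 10))
  if (anyDuplicated(key)) {
    stop("each direction must appear exactly once", call. = FALSE)
  }
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1]) {
    stop("`band` must be an increasing positive pair", call. = FALSE)
  }
  structure(
    list(sample_rate = sample_rate,
         directions = data.frame(azimuth = directions$azimuth,
                                 elevation = directions$elevation),
         left = left, right = right,
         frame = frame, band = band),
    class = "hrir_grid")
}

#' @export
print.hrir_grid <- function(x, ...) {
  cat(sprintf(
    "<hrir_grid> %d directions (%s frame), %d taps/ear at %g kHz, band %g-%g kHz\n",
    nrow(x$directions), x$frame, ncol(x$left), x$sample_rate / 1000,
    x$band[1] / 1000, x$band[2] / 1000))
  invisible(x)
}

n_directions <- function(grid) nrow(grid$directions)

# Index of a direction on the grid; exact match required (virtual sources
# must be synthesized for measured directions, never nearest-neighbour).
direction_index <- function(grid, azimuth, elevation, tol = 1e-6) {
  i <- which(abs(grid$directions$azimuth - azimuth) < tol &
             abs(grid$directions$elevation - elevation) < tol)
  if (length(i) != 1L) {
    stop(sprintf("direction (%g, %g) is not on the grid", azimuth, elevation),
         call. = FALSE)
  }
  i
}

# FFT length convention: next power of two >= 4x the IR length, fixed so
# magnitude values are reproducible bit-for-bit across calls.
grid_nfft <- function(grid) next_pow2(4L * ncol(grid$left))

#' Magnitude spectra of an HRIR grid
#'
#' Zero-padded FFT magnitude spectra (dB) per direction and ear, restricted
#' to the grid's analysis band. FFT length is the next power of two at or
#' above four times the impulse-response length.
#'
#' @param grid an [hrir_grid()].
#' @param floor_db magnitudes are floored at this level before conversion
#'   to dB to keep silent bins finite.
#' @return list with `frequency` (Hz, band bins), matrices `left_db`,
#'   `right_db` (direction x frequency), and `nfft`.
#' @export
grid_spectra <- function(grid, floor_db = -240) {
  nfft <- grid_nfft(grid)
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * grid$sample_rate / nfft
  in_band <- freq >= grid$band[1] & freq <= grid$band[2]
  if (!any(in_band)) stop("analysis band contains no FFT bins", call. = FALSE)
  if (grid$band[2] > grid$sample_rate / 2) {
    stop("analysis band exceeds the Nyquist frequency", call. = FALSE)
  }
  mag <- function(ir_mat) {
    sp <- stats::mvfft(t(cbind(ir_mat, matrix(0, nrow(ir_mat), nfft - ncol(ir_mat)))))
    m <- Mod(sp[seq_len(nfft %/% 2 + 1), , drop = FALSE])
    db <- 20 * log10(pmax(m, 10^(floor_db / 20)))
    t(db[in_band, , drop = FALSE])
  }
  list(frequency = freq[in_band],
       left_db = mag(grid$left),
       right_db = mag(grid$right),
       nfft = nfft)
}

# Band-average level (dB) per direction and ear; the fixed averaging
# convention is the mean of the dB magnitude spectrum over band bins.
band_levels <- function(grid) {
  sp <- grid_spectra(grid)
  list(left = rowMeans(sp$left_db), right = rowMeans(sp$right_db))
}
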