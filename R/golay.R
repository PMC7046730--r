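#' Generate a complementary Golay code pair
#'
#' Complementary (Golay) code pairs have autocorrelations that sum to a
#' perfect impulse: `2 * 2^order` at lag zero and exactly 0 elsewhere. This
#' property lets an impulse response be reconstructed from two probe
#' presentations with no deconvolution artifacts, the standard method for
#' acoustic head-related impulse response measurement.
#'
#' The pair is built by the doubling recursion
#' `a' = c(a, b)`, `b' = c(a, -b)` starting from `a = b = 1`.
#'
#' @param order integer `m >= 0`; each code has `2^m` points. The acoustic
#'   measurements this package models use `order = 16` (65,536 points).
#' @return object of class `"golay_pair"`: list with `code_a`, `code_b`
#'   (vectors of +-1) and `order`.
#' @examples
#' p <- generate_golay_pair(1) # a = (1, 1), b = (1, -1)
#' @export
generate_golay_pair <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 0 ||
      order != round(order)) {
    stop("`order` must be a non-negative integer", call. = FALSE)
  }
  a <- 1
  b <- 1
  for (i in seq_len(order)) {
    a_new <- c(a, b)
    b_new <- c(a, -b)
    a <- a_new
    b <- b_new
  }
  structure(list(code_a = a, code_b = b, order = as.integer(order)),
            class = "golay_pair")
}

#' Reconstruct an impulse response from Golay-code responses
#'
#' Given the recorded responses of a linear system to each code of a
#' complementary pair, cross-correlates each response with its own code,
#' sums, and normalizes by `2 * 2^order`. By the complementarity property
#' the result is the system's impulse response (exactly, for responses
#' produced by linear convolution with the codes).
#'
#' @param response_a,response_b recorded sample vectors, at least as long as
#'   the codes.
#' @param pair a [generate_golay_pair()] object.
#' @return numeric vector of impulse-response taps, length
#'   `length(response_a) - 2^order + 1`.
#' @export
reconstruct_hrir <- function(response_a, response_b, pair) {
  if (!inherits(pair, "golay_pair")) {
    stop("`pair` must be a golay_pair", call. = FALSE)
  }
  n <- length(pair$code_a)
  if (length(response_a) != length(response_b)) {
    stop("responses must have equal length", call. = FALSE)
  }
  if (length(response_a) < n) {
    stop("responses must be at least as long as the codes", call. = FALSE)
  }
  ca <- xcorr_nonneg(response_a, pair$code_a)
  cb <- xcorr_nonneg(response_b, pair$code_b)
  (ca + cb) / (2 * 2^pair$order)
}
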