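#' Freeze sound-localization cues of an HRIR grid
#'
#' Each freezing operation fixes exactly one cue at its reference value for
#' every direction while leaving the other cues to vary naturally:
#'
#' * `freeze_itd()`: interaural time difference set to zero by shifting the
#'   left-ear impulse response (integer samples) until its peak time equals
#'   the right ear's. Magnitude spectra are unchanged (shifts only move
#'   zeros in and out when the responses have silent edges, as measured and
#'   synthetic HRIRs here do).
#' * `freeze_ild()`: broadband interaural level difference set to zero by
#'   scaling each ear with a single scalar so that both band-average levels
#'   equal the two-ear mean. Spectral shapes and timing are unchanged.
#' * `freeze_spectrum()`: spectrum flattened by replacing each impulse
#'   response with a single-sample impulse at its original peak time,
#'   scaled to preserve that ear's band-average level; timing (hence ITD)
#'   and broadband ILD are preserved.
#' * `make_monaural()`: no signal to the ipsilateral (left) ear; the
#'   right-ear responses are unchanged. The broadband ILD becomes a capped
#'   sentinel (see [compute_ild()]).
#'
#' A frozen cue is still *present* at its reference value (zero ITD, equal
#' levels, flat spectrum); it is not erased, and may contradict the cues
#' that still vary.
#'
#' @param grid an [hrir_grid()].
#' @return a new [hrir_grid()] of the same shape.
#' @name cue_freezing
NULL

shift_ir <- function(h, s) {
  n <- length(h)
  if (s == 0) return(h)
  if (s > 0) c(numeric(s), h[seq_len(n - s)]) else c(h[(1 - s):n], numeric(-s))
}

#' @rdname cue_freezing
#' @export
freeze_itd <- function(grid) {
  stopifnot(inherits(grid, "hrir_grid"))
  out <- grid
  for (i in seq_len(n_directions(grid))) {
    tl <- which.max(abs(grid$left[i, ]))
    tr <- which.max(abs(grid$right[i, ]))
    out$left[i, ] <- shift_ir(grid$left[i, ], tr - tl)
  }
  out
}

#' @rdname cue_freezing
#' @export
freeze_ild <- function(grid) {
  stopifnot(inherits(grid, "hrir_grid"))
  lev <- band_levels(grid)
  if (any(!is.finite(lev$left)) || any(!is.finite(lev$right)) ||
      any(rowSums(grid$left^2) == 0) || any(rowSums(grid$right^2) == 0)) {
    stop("cannot equalize levels with a silent ear", call. = FALSE)
  }
  target <- (lev$left + lev$right) / 2
  out <- grid
  out$left <- grid$left * 10^((target - lev$left) / 20)
  out$right <- grid$right * 10^((target - lev$right) / 20)
  out
}

#' @rdname cue_freezing
#' @export
freeze_spectrum <- function(grid) {
  stopifnot(inherits(grid, "hrir_grid"))
  lev <- band_levels(grid)
  out <- grid
  L <- ncol(grid$left)
  flatten <- function(h, level_db) {
    if (all(h == 0)) return(numeric(L)) # silent ear stays silent
    imp <- numeric(L)
    imp[which.max(abs(h))] <- 10^(level_db / 20)
    imp
  }
  for (i in seq_len(n_directions(grid))) {
    out$left[i, ] <- flatten(grid$left[i, ], lev$left[i])
    out$right[i, ] <- flatten(grid$right[i, ], lev$right[i])
  }
  out
}

#' @rdname cue_freezing
#' @export
make_monaural <- function(grid) {
  stopifnot(inherits(grid, "hrir_grid"))
  out <- grid
  out$left[] <- 0
  out
}
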