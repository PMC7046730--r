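# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-(stream, index) sub-seed derivation, kept below 2^31.
derive_seed <- function(master_seed, ...) {
  idx <- c(...)
  s <- as.double(master_seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

next_pow2 <- function(n) {
  2L^as.integer(ceiling(log2(max(1, n))))
}

# Full linear convolution; length(x) + length(y) - 1.
conv_full <- function(x, y) {
  stats::convolve(x, rev(y), type = "open")
}

# Cross-correlation c[k] = sum_n x[n + k] * y[n]; returns lags 0 .. nx - ny
# (x must be at least as long as y).
xcorr_nonneg <- function(x, y) {
  cc <- conv_full(x, rev(y))
  cc[length(y):length(x)]
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rolling polynomial hash of the serialized object (mod 2^31 - 1); a stable
# hex digest used to stamp run provenance into output artifacts.
config_digest <- function(object) {
  raw <- as.double(serialize(object, connection = NULL, version = 2))
  p <- 2147483647
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% p
  sprintf("%08x", as.integer(h))
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
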