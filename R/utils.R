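# Internal helpers.

# Scoped RNG: seed the generator for a local stream and restore the caller's
# state afterwards, so library internals never perturb user-level
# reproducibility.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

# Run `expr` under a local seed, restoring RNG state on exit.
.with_seed <- function(seed, expr) {
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  expr
}

# Derive a bounded child seed from a master seed and stream indices,
# keeping the result well inside 32-bit integer range.
.child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 1e6
  for (k in seq_along(idx)) {
    s <- (s * 31 + as.numeric(idx[k]) * 101) %% 2147480000
  }
  as.integer(s %% 2147480000) + 1L
}

.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
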