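# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; if `seed` is
# NULL the current RNG stream is used (and advanced) as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive `n` child seeds from a master seed, all < 2^31, deterministically.
derive_seeds <- function(seed, n, salt = 0L) {
  with_seed(seed + salt, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(msg) stop(msg, call. = FALSE)
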