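# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed below 2^31 from a master seed.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.numeric(stream) * 12289L) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hs <- function(...) stop(sprintf(...), call. = FALSE)

check_prob <- function(p, what = "probability") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_hs("%s must lie in [0, 1]", what)
  }
  invisible(p)
}
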