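# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's random
# state. All exported generators route their randomness through this so that
# the same (model, seed) pair is bit-reproducible and nothing consumes the
# global stream.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000003 + stream * 7919) %% 2147483647L)
}

check_range <- function(x, lo, hi, what, id = NULL) {
  bad <- !is.na(x) & (x < lo | x > hi | x != floor(x))
  if (any(bad)) {
    where <- if (is.null(id)) which(bad)[1] else id[which(bad)[1]]
    stop(sprintf(
      "%s out of range [%d, %d] (first offender: %s, value %s)",
      what, lo, hi, as.character(where), as.character(x[bad][1])
    ), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
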