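# Internal helpers: seed substreams and small validators.

# Derive a reproducible sub-seed from one run seed and a stream name, so the
# cohort, the model and the solver can be re-seeded independently while all
# randomness still flows from a single user-supplied integer.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 69069 + h * 7919) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_prob_vector <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop(sprintf("'%s' must be a nonnegative probability vector summing to 1",
                 what), call. = FALSE)
  }
  invisible(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
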