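# Isolated, resumable RNG streams.
#
# Several components need their own reproducible randomness that must not
# disturb (or be disturbed by) the session RNG: learner weight init, the
# train/test exemplar streams of the multiple-choice task, scene noise.
# A stream snapshots `.Random.seed`, and `with_stream()` evaluates an
# expression under it, saving the advanced state back afterwards.

rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# deterministic sub-seed derivation (kept under 2^31)
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 13) %% 2147483629)
}
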