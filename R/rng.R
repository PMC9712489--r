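# Package-wide RNG protocol: every stochastic operation takes an explicit
# integer seed and evaluates under a locally seeded RNG, restoring the
# caller's RNG state afterwards. No hidden global state.

withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, staying inside
# 32-bit integer range.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483647)
}
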