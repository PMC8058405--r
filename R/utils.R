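# RNG scoping: operations that take an explicit seed evaluate their random
# draws under that seed and restore the caller's RNG state afterwards, so
# analysis randomness (subsampling, shuffles) never perturbs, and is never
# perturbed by, generator randomness.

local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation: one user-facing seed governs all draws
# via labelled streams (kept below 2^31 - 1).
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 7919 + h) %% 2147483629
}
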