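# Seed plumbing: one master seed spawns named substreams so that, e.g., adding
# patients to a cohort never perturbs the draws of existing patients.

# 32-bit helpers on doubles in [0, 2^32); all intermediates stay < 2^53, so
# the arithmetic is exact and identical on every platform.
xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  as.numeric(hi) * 65536 + as.numeric(lo)
}

mul32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
}

# murmur3-style avalanche finalizer: near-linear input seeds come out
# decorrelated, which matters because R scrambles set.seed() input only
# weakly -- linearly related stream seeds would give correlated draws.
fmix32 <- function(h) {
  h <- xor32(h, h %/% 65536)
  h <- mul32(h, 2246822507)
  h <- xor32(h, h %/% 8192)
  h <- mul32(h, 3266489909)
  xor32(h, h %/% 65536)
}

# Deterministic 31-bit mix of (seed, stream, id).
mix_seed <- function(seed, stream, id = 0L) {
  h <- as.numeric(seed) %% 4294967296
  h <- fmix32((h + mul32(2654435769, as.numeric(stream) %% 4294967296)) %%
                4294967296)
  h <- fmix32((h + mul32(2654435769, as.numeric(id) %% 4294967296)) %%
                4294967296)
  as.integer(h %% 2147483647)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
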