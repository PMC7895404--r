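# Internal helpers: deterministic string hashing and seed derivation.

# Polynomial rolling hash of a single string, modulo 2^31 - 1. Pure integer
# arithmetic on doubles (all intermediates < 2^53), so results are identical
# across platforms. Used for the deterministic "hash" rank predictor and for
# deriving independent per-key random substreams.
str_hash1 <- function(s, seed = 0) {
  m <- 2147483647
  h <- (abs(seed) %% m)
  x <- utf8ToInt(s)
  for (c in x) h <- (h * 131 + c) %% m
  # one extra scrambling round to decorrelate nearby keys
  h <- (h * 48271 + 11) %% m
  h
}

str_hash <- function(s, seed = 0) {
  vapply(s, str_hash1, numeric(1), seed = seed, USE.NAMES = FALSE)
}

# Derive a 32-bit-safe seed for a named substream from a master seed. Keyed
# by string so that adding or reordering streams never perturbs the others.
derive_seed <- function(master_seed, key) {
  as.integer(str_hash1(paste0(key, "#", master_seed)) %% 2147483646 + 1)
}

# Run `expr` with a locally derived seed, restoring the caller's RNG state.
with_substream <- function(master_seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(master_seed, key))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
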