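# Internal helpers: scoped RNG, labeled seed streams, config fingerprints.

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive one reproducible sub-seed per label from a master seed, so that
# components (split, pairs, probe genes, subset draws) are independently
# replayable. Sub-seeds stay within the 32-bit integer range.
spawn_seeds <- function(seed, labels) {
  s <- with_seed(seed, sample.int(2147483646L, length(labels)))
  stats::setNames(s, labels)
}

# Small deterministic fingerprint of a configuration list, for report sidecars.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                                 null = "null", force = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%09d", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
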