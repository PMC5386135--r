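# Deterministic per-replicate seed stream. Kept below 2^31 - 1; the mixing
# constant is a large prime so nearby (seed, index) pairs map far apart.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 1000003 + index + 1) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state, restoring the caller's stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
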