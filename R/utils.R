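# Internal helpers shared across modules.

# Full-precision numeric formatting for all text writers: %.17g survives a
# write -> read round trip bit-exactly for doubles.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Deterministic per-replicate seed stream derived from a single master seed.
# Counter-based so results do not depend on the order replicates are run in.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master_seed, replicate) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  as.integer((abs(as.double(master_seed)) + 999983 * as.double(replicate)) %%
    2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

assert_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
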