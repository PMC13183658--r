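# Internal helpers.

# Run `expr` under `set.seed(seed)` and restore the caller's RNG state
# afterwards, so seeded simulator calls do not perturb the session stream.
# seed = NULL uses the current stream untouched (for composed calls that
# seeded once at the top).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

# log-uniform draw on [lo, hi]
runif_log <- function(n, lo, hi) {
  exp(stats::runif(n, log(lo), log(hi)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
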