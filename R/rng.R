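#' Derive a labelled substream seed
#'
#' Deterministically maps a base seed and a consumer label to a new 31-bit
#' seed, so that independent consumers (data generation, candidate pools,
#' sign flips, slice updates) draw from non-colliding streams and changing
#' one consumer's settings does not perturb another's draws.
#'
#' @param seed integer base seed.
#' @param label character label of the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(label)) {
    h <- (h * 69069 + ch) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Run `expr` under `seed` (if non-NULL), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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
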