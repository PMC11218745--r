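# Internal helpers: seeded evaluation and seed-stream derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. With seed = NULL the expression runs on the
# current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline (scheduling, signal synthesis,
#' psychophysics, per-subject parameter draws) takes its own integer seed.
#' `derive_seed()` maps a master seed and a stream index to a child seed via a
#' fixed multiplicative hash so that any single stage can be reproduced without
#' replaying the whole study. Results stay within the 32-bit signed range.
#'
#' @param master Integer master seed.
#' @param stream Integer stream index (>= 0); distinct stages use distinct
#'   indices.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), is.numeric(stream), length(master) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  x <- (abs(master) %% m)
  for (k in c(stream + 1, 982451653)) {
    # 64-bit-safe modular muladd in doubles: split the multiplier
    x <- (x * 48271) %% m
    x <- (x + (k %% m)) %% m
  }
  as.integer(x)
}

# round half away from zero is not needed; base round() (banker's) is fine for
# sample-grid conversion because onsets are stored in seconds on a ms grid.
ms_to_samples <- function(ms, sample_rate) as.integer(round(ms / 1000 * sample_rate))

# clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
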