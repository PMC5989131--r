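#' Derive a per-operation substream seed from a global seed
#'
#' All randomness in the package flows from one user-supplied global seed.
#' Independent operations (taxonomy simulation, per-sample read draws, V6
#' read generation, bootstrap iterations, ...) each draw their own substream
#' seed with this counter scheme, so that changing one stage's stream index
#' never perturbs another stage's output.
#'
#' The scheme is `(31 * (seed mod M) + 7919 * stream + 1) mod M` with
#' `M = 2^31 - 1`, computed in double precision (exact for these magnitudes).
#' Results are always valid, positive, 32-bit R integers.
#'
#' @param seed integer global seed.
#' @param stream non-negative integer stream counter.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(stream), all(stream >= 0))
  m <- 2147483647
  s <- ((31 * (seed %% m)) %% m + (7919 * (stream %% m)) %% m + 1) %% m
  as.integer(ifelse(s == 0, 1, s))
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so package functions never
#' disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
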