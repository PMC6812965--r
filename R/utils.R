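## z-score with a zero-variance guard (returns centred zeros).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Derive independent sub-seeds from a master seed
#'
#' Deterministically expands one integer seed into `n` seeds for
#' independent simulation streams (all below 2^31).
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
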