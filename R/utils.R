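#' Derive a reproducible child seed
#'
#' Hierarchical seed derivation for the scenario -> replicate -> stage RNG
#' layout.  Mixing is a Lehmer-style congruential step modulo the Mersenne
#' prime 2^31 - 1, so every derived seed is a valid 32-bit integer seed and
#' adding a stage never perturbs the draws of a sibling stage.
#'
#' @param seed parent integer seed.
#' @param ... one or more non-negative integer indices (stage, replicate, ...).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(seed) %% m
  for (k in c(...)) {
    # 48271 * s < 2^47 and 9349 * k small: exact in double arithmetic
    s <- (s * 48271 + (as.double(k) %% m) * 9349 + 1) %% m
  }
  s <- floor(s)
  if (s < 1) s <- s + 1
  as.integer(s)
}

# equal-tailed 95% interval, type-7 quantiles (fixed convention, see vignette)
.ci95 <- function(x) unname(stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE))

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
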