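#' Relative bias of the posterior-median risk estimator
#'
#' `(mean(beta_hats) - beta_true) / beta_true`.
#'
#' @param beta_hats per-replicate posterior medians.
#' @param beta_true generating risk coefficient (nonzero).
#' @return the relative bias as a fraction.
#' @export
relative_bias <- function(beta_hats, beta_true) {
  .assert(is.numeric(beta_true) && length(beta_true) == 1L && beta_true != 0,
          "relative bias is undefined for beta_true = 0")
  (mean(beta_hats) - beta_true) / beta_true
}

#' Coverage rate of 95% credible intervals
#'
#' Fraction of replicate intervals `[lower, upper]` containing the
#' generating coefficient.
#'
#' @param lower,upper per-replicate interval bounds.
#' @param beta_true generating risk coefficient.
#' @return a fraction in `[0, 1]`.
#' @export
coverage_rate <- function(lower, upper, beta_true) {
  .assert(length(lower) == length(upper) && length(lower) >= 1L,
          "need at least one replicate interval")
  mean(lower <= beta_true & beta_true <= upper)
}

#' Statistical power against a null risk coefficient
#'
#' Fraction of replicate 95% credible intervals excluding 0 (entirely above
#' or entirely below).
#'
#' @inheritParams coverage_rate
#' @return a fraction in `[0, 1]`.
#' @export
statistical_power <- function(lower, upper) {
  .assert(length(lower) == length(upper) && length(lower) >= 1L,
          "need at least one replicate interval")
  mean(lower > 0 | upper < 0)
}

#' Pooled 95% interval across replicate chains
#'
#' Concatenates the retained draws of all replicates and takes the 2.5 and
#' 97.5 percentiles of the pooled chain.  Descriptive only: coverage is
#' always computed from per-replicate intervals.
#'
#' @param chains list of numeric draw vectors (or a single vector).
#' @return length-2 numeric interval.
#' @export
pooled_interval <- function(chains) {
  draws <- if (is.list(chains)) unlist(chains, use.names = FALSE) else chains
  .assert(length(draws) >= 1L, "no draws to pool")
  .ci95(draws)
}

#' DIC-based disease-model preference across replicates
#'
#' @param dic_ehr,dic_cox per-replicate DIC values of the excess-hazard-
#'   ratio and Cox-form fits.  Replicates with a missing DIC are excluded
#'   with a message.
#' @return list with `fraction_ehr` (share of replicates with strictly
#'   smaller EHR DIC), `mean_difference` (mean of DIC_EHR - DIC_Cox) and
#'   `n_used`.
#' @export
dic_preference <- function(dic_ehr, dic_cox) {
  .assert(length(dic_ehr) == length(dic_cox), "need paired DIC values")
  ok <- is.finite(dic_ehr) & is.finite(dic_cox)
  if (any(!ok)) message(sum(!ok), " replicate(s) excluded for missing DIC")
  .assert(any(ok), "no replicate has both DIC values")
  list(fraction_ehr = mean(dic_ehr[ok] < dic_cox[ok]),
       mean_difference = mean(dic_ehr[ok] - dic_cox[ok]),
       n_used = sum(ok))
}

#' Aggregate replicate-level fits into scenario metrics
#'
#' @param replicates data frame with columns `beta_hat`, `lower`, `upper`
#'   (one row per replicate, for one fitted form).
#' @param beta_true generating coefficient.
#' @param pooled_draws optional pooled chain for the descriptive interval.
#' @return one-row data frame with `n_replicates`, `mean_beta_hat`,
#'   `pooled_lower`, `pooled_upper`, `relative_bias`, `coverage`, `power`.
#' @export
summarize_scenario <- function(replicates, beta_true, pooled_draws = NULL) {
  ci <- if (is.null(pooled_draws)) c(NA_real_, NA_real_)
        else pooled_interval(pooled_draws)
  data.frame(n_replicates = nrow(replicates),
             mean_beta_hat = mean(replicates$beta_hat),
             pooled_lower = ci[1L], pooled_upper = ci[2L],
             relative_bias = relative_bias(replicates$beta_hat, beta_true),
             coverage = coverage_rate(replicates$lower, replicates$upper,
                                      beta_true),
             power = statistical_power(replicates$lower, replicates$upper))
}
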