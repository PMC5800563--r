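#' Piecewise-constant baseline hazard
#'
#' Constant lung-cancer mortality rate within age bands.  The default bands
#' split at ages 40/55/65/75 with rates rising steeply with age, in the
#' shape of population lung-cancer mortality; use [calibrate_baseline()] to
#' scale them to a target event yield in a given cohort.
#'
#' @param breaks increasing age cut-points including the support ends
#'   (default `c(0, 40, 55, 65, 75, 110)`).
#' @param rates per person-year rate in each of the `length(breaks) - 1`
#'   intervals, all >= 0.
#' @return an object of class `baseline_hazard`.
#' @export
baseline_hazard <- function(breaks = c(0, 40, 55, 65, 75, 110),
                            rates = c(2e-5, 4e-4, 1.5e-3, 3e-3, 4.5e-3)) {
  .assert(all(diff(breaks) > 0), "breaks must be strictly increasing")
  .assert(length(rates) == length(breaks) - 1L,
          "need one rate per interval between breaks")
  .assert(all(rates >= 0), "rates must be >= 0")
  structure(list(breaks = as.numeric(breaks), rates = as.numeric(rates)),
            class = "baseline_hazard")
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat("Piecewise-constant baseline hazard (per person-year):\n")
  for (k in seq_along(x$rates))
    cat(sprintf("  [%g, %g): %.3g\n", x$breaks[k], x$breaks[k + 1L], x$rates[k]))
  invisible(x)
}

#' Baseline rate at given ages
#'
#' @param baseline a [baseline_hazard()].
#' @param age numeric ages inside the support.
#' @return per person-year rates.
#' @export
baseline_rate <- function(baseline, age) {
  k <- findInterval(age, baseline$breaks, rightmost.closed = TRUE)
  .assert(all(k >= 1L & k <= length(baseline$rates)),
          "age outside the baseline hazard support")
  baseline$rates[k]
}

.ehr_forms <- c("D1", "D3", "D5")
.cox_forms <- c("D2", "D4", "D6")

#' Disease model linking cumulative exposure to the hazard
#'
#' The hazard is `h0(t) * g(Xcum(t))` with `Xcum` in units of 100 WLM and
#' `g(x) = 1 + eta(x)` for the excess-hazard-ratio (EHR) family (D1, D3, D5)
#' or `g(x) = exp(eta(x))` for the log-linear Cox family (D2, D4, D6), where
#' `eta` is linear (`beta * x`; D1/D2), a natural cubic spline anchored at
#' `eta(0) = 0` (D3/D4, requires `basis`), or continuous piecewise-linear
#' with a breakpoint (`beta[1] * min(x, c) + beta[2] * max(x - c, 0)`;
#' D5/D6, default breakpoint 1 model unit = 100 WLM).
#'
#' @param form one of `"D1"`..`"D6"`.
#' @param beta risk coefficient(s): scalar for D1/D2, length-2 for D5/D6,
#'   one per basis column for D3/D4.
#' @param breakpoint breakpoint for D5/D6 in model units of 100 WLM.
#' @param basis a `spline_basis` (see [select_spline_knots()]) for D3/D4.
#' @return an object of class `disease_model`.
#' @export
disease_model <- function(form, beta = NULL, breakpoint = 1.0, basis = NULL) {
  .assert(form %in% c(.ehr_forms, .cox_forms), "form must be one of D1..D6")
  if (form %in% c("D3", "D4"))
    .assert(inherits(basis, "spline_basis"), "D3/D4 require a spline_basis")
  structure(list(form = form,
                 family = if (form %in% .ehr_forms) "ehr" else "cox",
                 beta = beta, breakpoint = breakpoint, basis = basis),
            class = "disease_model")
}

#' Dose-response design matrix for a disease model
#'
#' Maps cumulative exposure `x` (units of 100 WLM) to the regressor columns
#' whose linear combination with `beta` gives `eta(x)`.
#'
#' @param model a [disease_model()].
#' @param x cumulative exposures.
#' @return numeric matrix with one row per element of `x`.
#' @export
dose_design <- function(model, x) {
  switch(model$form,
         D1 = , D2 = matrix(x, ncol = 1L),
         D5 = , D6 = cbind(pmin(x, model$breakpoint),
                           pmax(x - model$breakpoint, 0)),
         D3 = , D4 = spline_basis_matrix(model$basis, x))
}

# g(x) given coefficients; EHR forms return NA-free values that may be <= 0
.dose_response <- function(model, x, beta = model$beta) {
  eta <- drop(dose_design(model, x) %*% beta)
  if (model$family == "ehr") 1 + eta else exp(eta)
}

#' Hazard rate for one worker at given ages
#'
#' Evaluates `h0(t) * g(Xcum(t))` using the right-continuous cumulative
#' exposure step convention of [cumulative_exposure()].  For EHR forms an
#' error is raised if `g <= 0` at any requested age.
#'
#' @param model a [disease_model()] with coefficients set.
#' @param baseline a [baseline_hazard()].
#' @param history per-worker exposure data frame (columns `age`,
#'   `exposure_wlm`); pass the true history for data generation and the
#'   observed one for inference checks.
#' @param age numeric ages.
#' @param lag exposure lag (years).
#' @return hazard rates per person-year.
#' @export
hazard_at <- function(model, baseline, history, age, lag = 0) {
  x <- cumulative_exposure(history, age, lag)
  g <- .dose_response(model, x)
  if (model$family == "ehr")
    .assert(all(g > 0), "EHR hazard non-positive at a reachable exposure")
  baseline_rate(baseline, age) * g
}

#' Scale a baseline hazard to a target event yield
#'
#' Multiplies all interval rates by a common factor chosen by bisection so
#' that the expected number of events in the cohort -- under the given
#' disease model and the cohort's reference (error-free) exposure -- equals
#' `target_fraction * n_workers`.  The expectation is exact:
#' `sum_i (1 - exp(-H_i))` with `H_i` the closed-form cumulative hazard over
#' worker i's follow-up.
#'
#' @param baseline a [baseline_hazard()] giving the rate shape.
#' @param cohort a `miner_cohort`.
#' @param model a [disease_model()] with coefficients set.
#' @param target_fraction expected fraction of workers with an event.
#' @param lag exposure lag (years).
#' @return the scaled `baseline_hazard`.
#' @export
calibrate_baseline <- function(baseline, cohort, model,
                               target_fraction = 0.05, lag = 0) {
  .assert(target_fraction > 0 && target_fraction < 1,
          "target_fraction must be in (0, 1)")
  real <- apply_measurement_model(measurement_model("M0"), cohort)
  segs <- exposure_segments(real, baseline, exposure = "true", lag = lag)
  g <- .dose_response(model, segs$x)
  .assert(all(g > 0) || model$family == "cox",
          "dose-response non-positive on the cohort support")
  base_h <- baseline$rates[segs$k] * segs$dur * g
  H_i <- rowsum(base_h, segs$worker_id)    # per-worker cumulative hazard at m = 1
  target <- target_fraction * nrow(cohort$workers)
  f <- function(logm) sum(1 - exp(-exp(logm) * H_i)) - target
  lo <- -15; hi <- 15
  .assert(f(lo) < 0 && f(hi) > 0, "target event yield out of reachable range")
  m <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
  baseline_hazard(baseline$breaks, baseline$rates * m)
}
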