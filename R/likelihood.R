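#' Assemble likelihood data for a proportional-hazards fit
#'
#' Pre-computes everything the full-likelihood Metropolis-Hastings sampler
#' needs: constant-hazard segments over each worker's observed follow-up
#' `[entry, exit)`, the dose-response design matrix on segments and at event
#' times, per-baseline-interval aggregates, and (for excess-hazard-ratio
#' forms) a positivity-check grid over the observed exposure range.
#' Inference treats the chosen exposure side -- by default the observed one
#' -- as an error-free covariate.
#'
#' @param realization an `exposure_realization`.
#' @param outcomes survival records from [simulate_cohort_outcomes()].
#' @param baseline a [baseline_hazard()] fixing the age bands (rates are
#'   estimated unless fixed in [fit_model()]).
#' @param form disease-model form `"D1"`..`"D6"`.
#' @param breakpoint breakpoint for piecewise-linear forms (100 WLM units).
#' @param basis `spline_basis` for D3/D4; when `NULL` it is selected from
#'   the cases via [select_spline_knots()].
#' @param exposure which exposure column the fit sees (default
#'   `"observed"`).
#' @param lag exposure lag in years.
#' @return an object of class `ph_data`.
#' @export
ph_data <- function(realization, outcomes, baseline, form,
                    breakpoint = 1.0, basis = NULL,
                    exposure = c("observed", "true", "reference"), lag = 0) {
  exposure <- match.arg(exposure)
  .assert(nrow(outcomes) == nrow(realization$workers),
          "outcomes must have one record per worker")
  .assert(all(outcomes$exit_age > outcomes$entry_age),
          "exit must exceed entry for every worker")
  segs <- exposure_segments(realization, baseline, exposure, lag = lag,
                            end_age = outcomes$exit_age)
  # event rows: the worker's last segment carries Xcum(exit-) and the band
  last <- cumsum(tabulate(segs$worker_id, nrow(outcomes)))
  ev <- last[outcomes$event == 1L]
  if (form %in% c("D3", "D4") && is.null(basis)) {
    .assert(length(ev) >= 5L, "too few cases to place spline knots; enlarge the cohort")
    basis <- select_spline_knots(segs$x[ev])
  }
  template <- disease_model(form, breakpoint = breakpoint, basis = basis)
  seg_X <- dose_design(template, segs$x)
  ev_X <- dose_design(template, segs$x[ev])
  K <- length(baseline$rates)
  pos_grid <- NULL
  if (template$family == "ehr") {
    xg <- sort(unique(c(seq(0, max(segs$x), length.out = 201L), breakpoint,
                        if (!is.null(basis)) c(basis$interior, basis$boundary))))
    xg <- xg[xg <= max(segs$x)]
    pos_grid <- dose_design(template, xg)
  }
  structure(list(seg_k = segs$k, seg_dur = segs$dur, seg_X = seg_X,
                 ev_k = segs$k[ev], ev_X = ev_X,
                 n_ev_k = tabulate(segs$k[ev], K),
                 D = as.numeric(rowsum(segs$dur, factor(segs$k, levels = 1:K))),
                 S = rowsum(segs$dur * seg_X, factor(segs$k, levels = 1:K)),
                 py_k = as.numeric(rowsum(segs$dur, factor(segs$k, levels = 1:K))),
                 pos_grid = pos_grid,
                 K = K, p = ncol(seg_X),
                 n_workers = nrow(outcomes), n_events = length(ev),
                 form = form, family = template$family,
                 breakpoint = breakpoint, basis = basis,
                 baseline_breaks = baseline$breaks),
            class = "ph_data")
}

#' @export
print.ph_data <- function(x, ...) {
  cat(sprintf("ph_data: form %s, %d workers, %d events, %d segments, %d baseline bands\n",
              x$form, x$n_workers, x$n_events, length(x$seg_k), x$K))
  invisible(x)
}

#' Full log-likelihood of a proportional-hazards model
#'
#' Reference implementation of
#' `sum_i [ delta_i log h_i(exit_i) - int_entry^exit h_i(u) du ]` with the
#' integral evaluated exactly over the constant-hazard segments.  Returns
#' `-Inf` (rather than raising) when an excess-hazard-ratio form has a
#' non-positive hazard anywhere on the data.
#'
#' @param data a [ph_data()].
#' @param loglam log baseline rates, one per age band.
#' @param beta dose-response coefficient vector.
#' @return the log-likelihood value.
#' @export
log_likelihood <- function(data, loglam, beta) {
  .assert(length(loglam) == data$K, "need one log-rate per baseline band")
  eta_seg <- drop(data$seg_X %*% beta)
  eta_ev <- drop(data$ev_X %*% beta)
  if (data$family == "ehr") {
    g_seg <- 1 + eta_seg
    g_ev <- 1 + eta_ev
    if (any(g_seg <= 0) || any(g_ev <= 0)) return(-Inf)
    log_g_ev <- log(g_ev)
  } else {
    g_seg <- exp(eta_seg)
    log_g_ev <- eta_ev
  }
  sum(loglam[data$ev_k]) + sum(log_g_ev) -
    sum(exp(loglam)[data$seg_k] * data$seg_dur * g_seg)
}

# fast likelihood parts used by the sampler: per-interval loads A[k] such
# that the integral term is sum_k lambda_k A[k]; event term ev.
# EHR forms use the exact linear aggregation A = D + S beta and a grid
# positivity check; Cox forms use the fused C++ pass.
.ll_parts <- function(data, beta) {
  if (data$family == "ehr") {
    if (min(1 + drop(data$pos_grid %*% beta)) <= 0) return(NULL)
    g_ev <- 1 + drop(data$ev_X %*% beta)
    if (length(g_ev) && min(g_ev) <= 0) return(NULL)
    list(A = data$D + drop(data$S %*% beta), ev = sum(log(g_ev)))
  } else {
    list(A = cox_interval_loads(data$seg_k, data$seg_dur, data$seg_X,
                                beta, data$K),
         ev = sum(drop(data$ev_X %*% beta)))
  }
}

# log-likelihood from cached parts and current baseline
.ll_from_parts <- function(data, parts, loglam) {
  sum(data$n_ev_k * loglam) + parts$ev - sum(exp(loglam) * parts$A)
}
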