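#' Constant-hazard segments for every worker
#'
#' Splits each worker's follow-up `[hire age, end age)` at the ages where
#' either the baseline rate or cumulative exposure changes.  Cumulative
#' exposure is right-continuous: the year worked at age `[a, a + 1)` steps
#' the covariate at `a + 1` (+ lag).  On each resulting segment the total
#' hazard `h0(t) g(Xcum(t))` is constant, which the event-time simulator and
#' the likelihood exploit in closed form.
#'
#' @param realization an `exposure_realization` (or a `miner_cohort`, in
#'   which case the reference exposure is used).
#' @param baseline a [baseline_hazard()].
#' @param exposure which exposure column drives the covariate: `"true"`
#'   (data generation), `"observed"` (inference) or `"reference"`.
#' @param lag exposure lag in years.
#' @param end_age per-worker end of follow-up; defaults to the
#'   administrative censoring age.
#' @return data frame with one row per segment: `worker_id`, `k` (baseline
#'   interval index), `start` (age), `dur` (years), `x` (cumulative exposure
#'   in 100 WLM units on the segment).
#' @export
exposure_segments <- function(realization, baseline,
                              exposure = c("true", "observed", "reference"),
                              lag = 0, end_age = NULL) {
  exposure <- match.arg(exposure)
  col <- switch(exposure, true = "exposure_true_wlm",
                observed = "exposure_obs_wlm", reference = "exposure_wlm")
  exp_df <- realization$exposure
  if (is.null(exp_df[[col]]) && exposure != "reference")
    stop("realization lacks column ", col, call. = FALSE)
  if (is.null(exp_df[[col]])) col <- "exposure_wlm"
  workers <- realization$workers
  n <- nrow(workers)
  if (is.null(end_age)) end_age <- workers$censor_age
  .assert(length(end_age) == n, "end_age must have one entry per worker")
  .assert(all(end_age > workers$hire_age), "end of follow-up must exceed hire age")

  bb <- baseline$breaks
  inner <- bb[-c(1L, length(bb))]
  # exposure rows are stored in consecutive per-worker blocks
  idx_end <- cumsum(workers$n_years)
  idx_start <- c(1L, idx_end[-n] + 1L)
  wlm <- exp_df[[col]]

  out <- vector("list", n)
  for (i in seq_len(n)) {
    entry <- workers$hire_age[i]
    end <- end_age[i]
    m <- workers$n_years[i]
    xs <- c(0, cumsum(wlm[idx_start[i]:idx_end[i]])) / 100
    sa <- entry + lag + seq_len(m)            # covariate step ages
    b <- sort(unique(c(entry,
                       sa[sa > entry & sa < end],
                       inner[inner > entry & inner < end],
                       end)))
    nb <- length(b) - 1L
    bs <- b[-length(b)]
    out[[i]] <- list(worker_id = rep.int(i, nb),
                     k = findInterval(bs, bb, rightmost.closed = TRUE),
                     start = bs,
                     dur = diff(b),
                     x = xs[findInterval(bs, sa) + 1L])
  }
  data.frame(worker_id = unlist(lapply(out, `[[`, "worker_id")),
             k = unlist(lapply(out, `[[`, "k")),
             start = unlist(lapply(out, `[[`, "start")),
             dur = unlist(lapply(out, `[[`, "dur")),
             x = unlist(lapply(out, `[[`, "x")))
}

#' Simulate one event time by exact cumulative-hazard inversion
#'
#' Solves `integral_entry^t h(u) du = E` on the worker's constant-hazard
#' segments: the cumulative hazard is continuous piecewise-linear, so the
#' crossing is found in closed form on the segment where it occurs.
#'
#' @param hk hazard rate on each segment (per person-year).
#' @param start,dur segment start ages and durations.
#' @param censor_age administrative censoring age.
#' @param E exponential(1) draw.
#' @return list with `exit_age` and `event` (1 = failure, 0 = censored).
#' @export
invert_cumulative_hazard <- function(hk, start, dur, censor_age, E) {
  H <- cumsum(hk * dur)
  j <- which(H >= E)
  if (length(j) == 0L) return(list(exit_age = censor_age, event = 0L))
  j <- j[1L]
  H0 <- if (j == 1L) 0 else H[j - 1L]
  t <- start[j] + (E - H0) / hk[j]
  list(exit_age = t, event = 1L)
}

#' Simulate one worker's event or censoring time
#'
#' Draws `E ~ Exponential(1)` and solves
#' `integral_entry^t h(u) du = E` over the worker's constant-hazard
#' segments; administrative censoring applies if the cumulative hazard
#' never reaches `E`.
#'
#' @param model a [disease_model()] with coefficients set.
#' @param baseline a [baseline_hazard()].
#' @param history the worker's exposure data frame (columns `age`,
#'   `exposure_wlm`); drives the hazard as the true exposure.
#' @param entry_age,censor_age follow-up bounds (`entry_age < censor_age`).
#' @param seed integer seed for the exponential draw.
#' @param lag exposure lag in years.
#' @return list with `entry_age`, `exit_age` and `event`.
#' @export
simulate_event_time <- function(model, baseline, history, entry_age,
                                censor_age, seed = 1L, lag = 0) {
  .assert(entry_age < censor_age, "entry must precede censoring")
  set.seed(seed)
  E <- stats::rexp(1)
  sa <- if (nrow(history)) history$age + 1 + lag else numeric(0)
  bb <- baseline$breaks
  inner <- bb[-c(1L, length(bb))]
  b <- sort(unique(c(entry_age,
                     sa[sa > entry_age & sa < censor_age],
                     inner[inner > entry_age & inner < censor_age],
                     censor_age)))
  bs <- b[-length(b)]
  x <- vapply(bs, function(t) sum(history$exposure_wlm[sa <= t]), 0) / 100
  g <- .dose_response(model, x)
  if (model$family == "ehr")
    .assert(all(g > 0), "EHR hazard non-positive at a reachable exposure")
  hk <- baseline$rates[findInterval(bs, bb, rightmost.closed = TRUE)] * g
  out <- invert_cumulative_hazard(hk, bs, diff(b), censor_age, E)
  list(entry_age = entry_age, exit_age = out$exit_age, event = out$event)
}

#' Simulate event or censoring times for a whole cohort
#'
#' Failure times are generated from the TRUE exposure side of the
#' realization under the given disease model; censoring is administrative.
#' All exponential draws are made up front from the seed (one per worker,
#' in worker order), so two models compared under the same seed use common
#' random numbers.
#'
#' @param model a [disease_model()] with coefficients set.
#' @param baseline a [baseline_hazard()].
#' @param realization an `exposure_realization`.
#' @param seed integer seed.
#' @param lag exposure lag in years.
#' @return data frame of survival records: `worker_id`, `entry_age`,
#'   `exit_age`, `event`; attribute `n_events` records the yield.
#' @export
simulate_cohort_outcomes <- function(model, baseline, realization, seed = 1L,
                                     lag = 0) {
  workers <- realization$workers
  n <- nrow(workers)
  set.seed(seed)
  E <- stats::rexp(n)
  segs <- exposure_segments(realization, baseline, "true", lag = lag)
  g <- .dose_response(model, segs$x)
  if (model$family == "ehr")
    .assert(all(g > 0), "EHR hazard non-positive at a reachable exposure")
  hk <- baseline$rates[segs$k] * segs$dur * g   # per-segment hazard mass
  # closed-form inversion, vectorised over workers via per-worker blocks
  exit <- workers$censor_age
  event <- integer(n)
  Hc <- cumsum(hk)
  last <- cumsum(tabulate(segs$worker_id, n))
  first <- c(1L, last[-n] + 1L)
  base <- c(0, Hc[last])[seq_len(n)]            # cumulative mass before worker i
  Hrel_end <- Hc[last] - base
  hit <- E < Hrel_end
  for (i in which(hit)) {
    rng <- first[i]:last[i]
    H <- Hc[rng] - base[i]
    j <- which(H >= E[i])[1L]
    H0 <- if (j == 1L) 0 else H[j - 1L]
    rate <- baseline$rates[segs$k[rng[j]]] * g[rng[j]]
    exit[i] <- segs$start[rng[j]] + (E[i] - H0) / rate
    event[i] <- 1L
  }
  out <- data.frame(worker_id = workers$worker_id,
                    entry_age = workers$hire_age,
                    exit_age = exit, event = event)
  attr(out, "n_events") <- sum(event)
  out
}
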