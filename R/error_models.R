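#' One multiplicative log-normal error layer
#'
#' A layer is described by its direction (Berkson: true = reference x U;
#' classical: observed = reference x U), its sharing structure and its
#' log-scale variance.  Log errors are normal with mean `-sigma2/2`, so
#' `E(U) = 1` exactly.
#'
#' @param type `"berkson"` or `"classical"`.
#' @param sharing draw granularity: `"unshared"` (one draw per worker-year),
#'   `"between"` (one per group-year), `"within"` (one per worker), or
#'   `"both"` (one per group).
#' @param sigma2 log-scale variance, >= 0.
#' @param periods exposure periods the layer applies to (subset of 1:3);
#'   years outside receive error exactly 1.
#' @return an object of class `error_layer`.
#' @export
error_layer <- function(type = c("berkson", "classical"),
                        sharing = c("unshared", "between", "within", "both"),
                        sigma2, periods = 1:3) {
  type <- match.arg(type)
  sharing <- match.arg(sharing)
  .assert(is.numeric(sigma2) && length(sigma2) == 1L && sigma2 >= 0,
          "sigma2 must be a single value >= 0")
  .assert(length(periods) >= 1L && all(periods %in% 1:3),
          "periods must be a nonempty subset of 1:3")
  structure(list(type = type, sharing = sharing, sigma2 = sigma2,
                 periods = as.integer(periods)),
            class = "error_layer")
}

#' Sample a multiplicative error field for a cohort index
#'
#' Draws one log-normal error per unit of the layer's sharing index set and
#' replicates it across the set.  Rows outside the layer's periods get error
#' exactly 1.  Draw order is tied to the sorted unique key, so the field is
#' invariant to row order.
#'
#' @param layer an [error_layer()].
#' @param index data frame with columns `worker_id`, `group_id`,
#'   `calendar_year`, `period` (one row per worker-year in scope).
#' @param seed integer seed.
#' @return numeric vector of multiplicative errors aligned with `index` rows.
#' @export
sample_error_field <- function(layer, index, seed) {
  u <- rep(1, nrow(index))
  in_scope <- index$period %in% layer$periods
  if (!any(in_scope) || layer$sigma2 == 0) return(u)
  key <- switch(layer$sharing,
                unshared = paste(index$worker_id, index$calendar_year),
                between  = paste(index$group_id, index$calendar_year),
                within   = as.character(index$worker_id),
                both     = as.character(index$group_id))
  key <- key[in_scope]
  uk <- sort(unique(key))
  s <- sqrt(layer$sigma2)
  set.seed(seed)
  draws <- exp(stats::rnorm(length(uk), -layer$sigma2 / 2, s))
  u[in_scope] <- draws[match(key, uk)]
  u
}

.realization <- function(cohort, true_wlm, obs_wlm, model_id) {
  out <- cohort$exposure
  out$exposure_true_wlm <- true_wlm
  out$exposure_obs_wlm <- obs_wlm
  .assert(all(out$exposure_true_wlm >= 0) && all(out$exposure_obs_wlm >= 0),
          "exposures must be non-negative")
  structure(list(exposure = out, workers = cohort$workers,
                 config = cohort$config, model_id = model_id),
            class = "exposure_realization")
}

#' @export
print.exposure_realization <- function(x, ...) {
  cat(sprintf("Exposure realization under %s: %d worker-years\n",
              x$model_id, nrow(x$exposure)))
  invisible(x)
}

#' Apply an error field in the Berkson direction
#'
#' Observed exposure is the reference; true exposure is reference x U.
#' Typical of group-level exposure assignment: individual truth varies
#' around the assigned value, `E(X | Z) = Z`.
#'
#' @param cohort a `miner_cohort` providing the reference exposure history.
#' @param u multiplicative errors aligned with `cohort$exposure` rows.
#' @param model_id label stored on the realization.
#' @return an `exposure_realization` with columns `exposure_true_wlm` and
#'   `exposure_obs_wlm` added to the worker-year table.
#' @export
apply_berkson <- function(cohort, u, model_id = "berkson") {
  .assert(length(u) == nrow(cohort$exposure),
          "error field must cover every exposure record")
  ref <- cohort$exposure$exposure_wlm
  .realization(cohort, true_wlm = ref * u, obs_wlm = ref, model_id)
}

#' Apply an error field in the classical direction
#'
#' True exposure is the reference; observed exposure is reference x U.
#' Typical of instrument measurement: `E(Z | X) = X`, and the variability of
#' observed exposure exceeds that of true exposure.
#'
#' @inheritParams apply_berkson
#' @return an `exposure_realization`.
#' @export
apply_classical <- function(cohort, u, model_id = "classical") {
  .assert(length(u) == nrow(cohort$exposure),
          "error field must cover every exposure record")
  ref <- cohort$exposure$exposure_wlm
  .realization(cohort, true_wlm = ref, obs_wlm = ref * u, model_id)
}

# sharing structure of the single homoscedastic layer for M1..M8
.m18 <- list(M1 = c("berkson", "unshared"),  M2 = c("classical", "unshared"),
             M3 = c("berkson", "between"),   M4 = c("classical", "between"),
             M5 = c("berkson", "within"),    M6 = c("classical", "within"),
             M7 = c("berkson", "both"),      M8 = c("classical", "both"))

#' Construct a measurement model M0-M11
#'
#' `M0` is the error-free identity.  `M1`-`M8` carry one homoscedastic layer
#' over all periods: Berkson (odd ids) or classical (even ids), unshared
#' (M1/M2), shared between workers (M3/M4), shared within workers (M5/M6) or
#' shared both between and within (M7/M8); `sigma2` is its log-scale
#' variance.  The heteroscedastic models take period-specific variances
#' `sigma2 = c(s1, s2, s3)`:
#' \describe{
#'   \item{M9}{unshared Berkson error in periods 1 and 2, unshared classical
#'     error in period 3; the period-1 reference is first collapsed to one
#'     value per group (retrospective reconstruction assigns a single
#'     estimate to all years of a group).}
#'   \item{M10}{latent true group means in periods 1 and 2; true exposure
#'     adds unshared Berkson noise, observed exposure adds shared classical
#'     noise from the measuring device (`sigma2_shared = c(s1s, s2s)`:
#'     per-group in period 1, per-group-year in period 2); period 3 unshared
#'     classical.}
#'   \item{M11}{observed exposure is the reference; true exposure multiplies
#'     unshared Berkson noise and a per-worker Berkson factor shared across
#'     a worker's years (`sigma2_shared`, by period 1/2), reflecting
#'     individual worker practices; period 3 unshared classical.}
#' }
#' Custom models can be given as an explicit list of [error_layer()]s with
#' `measurement_model("custom", layers = ...)` (all layers Berkson or all
#' classical).
#'
#' @param model_id one of `"M0"`..`"M11"` or `"custom"`.
#' @param sigma2 layer variance (scalar for M1-M8; length-3 per-period vector
#'   for M9-M11).
#' @param sigma2_shared length-2 vector of shared-layer variances for
#'   M10/M11 (periods 1 and 2).
#' @param layers list of [error_layer()]s for `"custom"`.
#' @param group_value how the single period-1 group value is formed for
#'   M9/M10: `"mean"` (default) or `"median"` of the group's period-1
#'   reference exposures.
#' @return an object of class `measurement_model`.
#' @export
measurement_model <- function(model_id,
                              sigma2 = NULL,
                              sigma2_shared = c(0.81, 0.12),
                              layers = NULL,
                              group_value = c("mean", "median")) {
  group_value <- match.arg(group_value)
  if (model_id == "M0") {
    mod <- list(model_id = "M0", layers = list())
  } else if (model_id %in% names(.m18)) {
    .assert(!is.null(sigma2) && length(sigma2) == 1L,
            sprintf("%s needs a scalar sigma2", model_id))
    ts <- .m18[[model_id]]
    mod <- list(model_id = model_id,
                layers = list(error_layer(ts[1L], ts[2L], sigma2)))
  } else if (model_id %in% c("M9", "M10", "M11")) {
    if (is.null(sigma2))
      sigma2 <- if (model_id == "M9") c(0.8, 0.15, 0.01) else c(0.09, 0.03, 0.01)
    .assert(length(sigma2) == 3L, sprintf("%s needs sigma2 of length 3", model_id))
    .assert(length(sigma2_shared) == 2L,
            "sigma2_shared must have length 2 (periods 1 and 2)")
    mod <- list(model_id = model_id, sigma2 = sigma2,
                sigma2_shared = sigma2_shared, group_value = group_value)
  } else if (model_id == "custom") {
    .assert(is.list(layers) && length(layers) >= 1L &&
              all(vapply(layers, inherits, TRUE, "error_layer")),
            "custom models need a nonempty list of error_layer objects")
    .assert(length(unique(vapply(layers, `[[`, "", "type"))) == 1L,
            "custom layers must share one error direction")
    mod <- list(model_id = "custom", layers = layers)
  } else stop("unknown measurement model id: ", model_id, call. = FALSE)
  class(mod) <- "measurement_model"
  mod
}

#' @export
print.measurement_model <- function(x, ...) {
  cat("Measurement model", x$model_id, "\n")
  if (!is.null(x$layers)) for (l in x$layers)
    cat(sprintf("  %s %s sigma2=%g periods=%s\n", l$sharing, l$type, l$sigma2,
                paste(l$periods, collapse = ",")))
  if (!is.null(x$sigma2))
    cat(sprintf("  per-period sigma2 = %s; shared sigma2 = %s\n",
                paste(x$sigma2, collapse = "/"),
                paste(x$sigma2_shared, collapse = "/")))
  invisible(x)
}

# one value per group from period-1 reference exposures (retrospective
# reconstruction estimates a single level for all years of a group)
.group_period1_value <- function(exposure, fun) {
  p1 <- exposure$period == 1L
  if (!any(p1)) return(numeric(0))
  tapply(exposure$exposure_wlm[p1], exposure$group_id[p1], fun)
}

# group(-year) means used as latent true levels in M10
.group_year_value <- function(exposure, rows, fun) {
  key <- paste(exposure$group_id[rows], exposure$calendar_year[rows])
  ave <- tapply(exposure$exposure_wlm[rows], key, fun)
  as.numeric(ave[key])
}

#' Apply a measurement model to a cohort
#'
#' Turns the cohort's reference exposure history into a (true, observed)
#' pair.  Under Berkson-type models the observed history equals the
#' reference; under classical-type models the true history does.  Layer
#' seeds are derived hierarchically from `seed`, so adding a layer never
#' perturbs another layer's draws.
#'
#' @param model a [measurement_model()].
#' @param cohort a `miner_cohort`.
#' @param seed integer seed.
#' @return an `exposure_realization`.
#' @export
apply_measurement_model <- function(model, cohort, seed = 1L) {
  .assert(inherits(model, "measurement_model"), "model must be a measurement_model")
  exposure <- cohort$exposure
  ref <- exposure$exposure_wlm
  id <- model$model_id

  if (id == "M0")
    return(.realization(cohort, ref, ref, "M0"))

  if (!is.null(model$layers)) {           # M1..M8 and custom: one direction
    u <- rep(1, nrow(exposure))
    for (k in seq_along(model$layers))
      u <- u * sample_error_field(model$layers[[k]], exposure,
                                  derive_seed(seed, k))
    dir <- model$layers[[1L]]$type
    return(if (dir == "berkson") apply_berkson(cohort, u, id)
           else apply_classical(cohort, u, id))
  }

  # heteroscedastic three-period models
  s2 <- model$sigma2
  fun <- match.fun(model$group_value)
  p1 <- exposure$period == 1L
  p2 <- exposure$period == 2L
  p3 <- exposure$period == 3L
  u1 <- sample_error_field(error_layer("berkson", "unshared", s2[1L], 1L),
                           exposure, derive_seed(seed, 1L))
  u2 <- sample_error_field(error_layer("berkson", "unshared", s2[2L], 2L),
                           exposure, derive_seed(seed, 2L))
  u3 <- sample_error_field(error_layer("classical", "unshared", s2[3L], 3L),
                           exposure, derive_seed(seed, 3L))

  true_wlm <- ref
  obs_wlm <- ref
  if (id == "M9") {
    # single reconstructed value per group in period 1
    z1 <- .group_period1_value(exposure, fun)
    base1 <- if (any(p1)) as.numeric(z1[as.character(exposure$group_id[p1])]) else numeric(0)
    obs_wlm[p1] <- base1
    true_wlm[p1] <- base1 * u1[p1]
    true_wlm[p2] <- ref[p2] * u2[p2]
    obs_wlm[p3] <- ref[p3] * u3[p3]
  } else if (id == "M10") {
    us1 <- sample_error_field(error_layer("classical", "both",
                                          model$sigma2_shared[1L], 1L),
                              exposure, derive_seed(seed, 4L))
    us2 <- sample_error_field(error_layer("classical", "between",
                                          model$sigma2_shared[2L], 2L),
                              exposure, derive_seed(seed, 5L))
    chi1 <- .group_period1_value(exposure, fun)
    lat1 <- if (any(p1)) as.numeric(chi1[as.character(exposure$group_id[p1])]) else numeric(0)
    lat2 <- .group_year_value(exposure, p2, fun)
    true_wlm[p1] <- lat1 * u1[p1]
    obs_wlm[p1] <- lat1 * us1[p1]
    true_wlm[p2] <- lat2 * u2[p2]
    obs_wlm[p2] <- lat2 * us2[p2]
    obs_wlm[p3] <- ref[p3] * u3[p3]
  } else if (id == "M11") {
    us1 <- sample_error_field(error_layer("berkson", "within",
                                          model$sigma2_shared[1L], 1L),
                              exposure, derive_seed(seed, 4L))
    us2 <- sample_error_field(error_layer("berkson", "within",
                                          model$sigma2_shared[2L], 2L),
                              exposure, derive_seed(seed, 5L))
    true_wlm[p1] <- ref[p1] * u1[p1] * us1[p1]
    true_wlm[p2] <- ref[p2] * u2[p2] * us2[p2]
    obs_wlm[p3] <- ref[p3] * u3[p3]
  }
  .realization(cohort, true_wlm, obs_wlm, id)
}

#' Read a measurement model from a YAML or JSON file
#'
#' The file either names a standard model (`model: M1` with `sigma2` etc.)
#' or declares `model: custom` with a `layers` list whose entries carry
#' `type`, `sharing`, `sigma2` and optionally `periods`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `measurement_model`.
#' @export
measurement_model_from_file <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  id <- spec$model
  .assert(!is.null(id), "config must name a 'model'")
  if (identical(id, "custom")) {
    layers <- lapply(spec$layers, function(l)
      error_layer(l$type, l$sharing, l$sigma2,
                  if (is.null(l$periods)) 1:3 else unlist(l$periods)))
    return(measurement_model("custom", layers = layers))
  }
  args <- list(model_id = id)
  for (f in c("sigma2", "sigma2_shared", "group_value"))
    if (!is.null(spec[[f]])) args[[f]] <- unlist(spec[[f]])
  do.call(measurement_model, args)
}

#' Total log-scale error variance by exposure period
#'
#' Sums the log-normal layer variances of a measurement model per period
#' (independent layers add on the log scale) and reports an
#' exposure-weighted global variance, the quantity used to match a
#' homoscedastic variance to a heteroscedastic setting.
#'
#' @param model a [measurement_model()].
#' @param cohort optional `miner_cohort`; when supplied, periods are
#'   weighted by their total reference exposure, otherwise equally.
#' @return data frame with columns `period`, `total_sigma2`, and attribute
#'   `global_sigma2`.
#' @export
total_log_error_variance <- function(model, cohort = NULL) {
  per <- numeric(3)
  if (!is.null(model$layers)) {
    for (l in model$layers) per[l$periods] <- per[l$periods] + l$sigma2
  } else if (!is.null(model$sigma2)) {
    per <- model$sigma2
    if (model$model_id %in% c("M10", "M11"))
      per[1:2] <- per[1:2] + model$sigma2_shared
  }
  w <- if (is.null(cohort)) rep(1, 3) else
    vapply(1:3, function(q)
      sum(cohort$exposure$exposure_wlm[cohort$exposure$period == q]), 0)
  out <- data.frame(period = 1:3, total_sigma2 = per)
  attr(out, "global_sigma2") <- sum(per * w) / sum(w)
  out
}
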