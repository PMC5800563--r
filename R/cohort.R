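#' Configuration for the synthetic miner cohort generator
#'
#' Describes an occupational cohort with three exposure-assessment periods:
#' an early retrospective reconstruction (period 1), a prospective group-level
#' assessment (period 2) and individual dosimetry (period 3).  Annual exposure
#' follows a calendar-year trend: a plateau over period 1 and an exponential
#' decay afterwards, anchored so that the mean annual exposure equals
#' `plateau_wlm` in the last plateau year and `final_wlm` in `final_year`.
#' Individual annual exposures are drawn log-normally around this trend with
#' log-scale standard deviation `exposure_dispersion`; the mean-correction
#' `-s^2/2` makes the trend the arithmetic mean.
#'
#' @param n_workers number of workers.
#' @param n_groups number of job-category groups; workers are assigned
#'   uniformly at random (only the sharing index structure matters for the
#'   error models).
#' @param period_bounds two increasing calendar years; years `<= bound[1]`
#'   are period 1, years in `(bound[1], bound[2]]` period 2, later years
#'   period 3.
#' @param hire_year_range calendar interval from which hire years are drawn
#'   uniformly (integer years).
#' @param hire_age_mean,hire_age_sd,hire_age_limits normal location/scale for
#'   age at hire (years), truncated to `hire_age_limits`.
#' @param employment_mean,employment_sd normal location/scale of employment
#'   duration (whole years), truncated below at 1.
#' @param plateau_wlm mean annual exposure (WLM) during the period-1 plateau.
#' @param final_wlm mean annual exposure (WLM) in `final_year`.
#' @param final_year last year of mining; employment years are clipped here.
#' @param exposure_dispersion log-scale SD of annual exposures around the
#'   trend (>= 0).
#' @param admin_censor_year administrative end of follow-up.
#' @param max_age upper age limit of follow-up (years).
#' @param exposure_lag lag (years) between receiving an annual exposure and
#'   it entering cumulative exposure; default 0.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_workers = 5086L,
                          n_groups = 10L,
                          period_bounds = c(1955L, 1982L),
                          hire_year_range = c(1945L, 1999L),
                          hire_age_mean = 25, hire_age_sd = 5,
                          hire_age_limits = c(16, 50),
                          employment_mean = 17, employment_sd = 8,
                          plateau_wlm = 28.28, final_wlm = 0.14,
                          final_year = 1999L,
                          exposure_dispersion = 1.0,
                          admin_censor_year = 2007L,
                          max_age = 85,
                          exposure_lag = 0) {
  cfg <- list(n_workers = as.integer(n_workers), n_groups = as.integer(n_groups),
              period_bounds = as.integer(period_bounds),
              hire_year_range = as.integer(hire_year_range),
              hire_age_mean = hire_age_mean, hire_age_sd = hire_age_sd,
              hire_age_limits = hire_age_limits,
              employment_mean = employment_mean, employment_sd = employment_sd,
              plateau_wlm = plateau_wlm, final_wlm = final_wlm,
              final_year = as.integer(final_year),
              exposure_dispersion = exposure_dispersion,
              admin_censor_year = as.integer(admin_censor_year),
              max_age = max_age, exposure_lag = exposure_lag)
  .assert(cfg$n_workers >= 1L, "n_workers must be a positive count")
  .assert(cfg$n_groups >= 1L && cfg$n_groups <= cfg$n_workers,
          "n_groups must satisfy 1 <= n_groups <= n_workers")
  .assert(length(cfg$period_bounds) == 2L && diff(cfg$period_bounds) > 0L,
          "period_bounds must be two strictly increasing calendar years")
  .assert(diff(cfg$hire_year_range) >= 0L, "hire_year_range must be non-decreasing")
  .assert(cfg$hire_age_sd >= 0 && cfg$employment_sd >= 0 &&
            cfg$exposure_dispersion >= 0,
          "all scale parameters must be >= 0")
  .assert(cfg$plateau_wlm > 0 && cfg$final_wlm > 0,
          "exposure anchors must be positive")
  .assert(cfg$final_year > cfg$period_bounds[1L],
          "final_year must lie after the period-1 plateau")
  .assert(cfg$admin_censor_year >= cfg$hire_year_range[2L],
          "admin_censor_year must not precede the last hire year")
  class(cfg) <- "cohort_config"
  cfg
}

#' Mean annual exposure trend (WLM) by calendar year
#'
#' Constant at `plateau_wlm` up to the first period bound, then exponential
#' decay reaching `final_wlm` in `final_year`.
#'
#' @param config a [cohort_config()].
#' @param years integer calendar years.
#' @return numeric vector of mean annual exposures (WLM).
#' @export
exposure_trend <- function(config, years) {
  p1_end <- config$period_bounds[1L]
  rate <- log(config$final_wlm / config$plateau_wlm) / (config$final_year - p1_end)
  ifelse(years <= p1_end,
         config$plateau_wlm,
         config$plateau_wlm * exp(rate * (years - p1_end)))
}

# truncated-normal draw by inverse CDF (exact, vectorised)
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic occupational cohort
#'
#' Draws hire year, hire age, employment duration and group membership for
#' each worker and one annual exposure value for every employment year.
#' Employment years are clipped at `final_year`.  Follow-up runs from hire
#' age to the administrative censoring age
#' `min(hire_age + (admin_censor_year - hire_year), max_age)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer RNG seed; identical seed and config give a
#'   bit-identical cohort.
#' @return an object of class `miner_cohort`: a list with elements
#'   `workers` (one row per worker: `worker_id`, `group_id`, `hire_year`,
#'   `hire_age`, `duration_drawn` (employment duration before clipping at
#'   `final_year`), `n_years` (realized employment years), `censor_age`),
#'   `exposure` (one row per
#'   worker-year: `worker_id`, `group_id`, `calendar_year`, `age`, `period`,
#'   `exposure_wlm`, where `age` is the age at the start of the year),
#'   `config` and `seed`.
#' @export
generate_cohort <- function(config, seed = 1L) {
  .assert(inherits(config, "cohort_config"), "config must be a cohort_config")
  set.seed(seed)
  n <- config$n_workers
  hy <- config$hire_year_range
  hire_year <- if (hy[1L] == hy[2L]) rep(hy[1L], n) else
    sample(seq.int(hy[1L], hy[2L]), n, replace = TRUE)
  hire_age <- .rtnorm(n, config$hire_age_mean, config$hire_age_sd,
                      config$hire_age_limits[1L], config$hire_age_limits[2L])
  dur <- pmax(1, round(.rtnorm(n, config$employment_mean, config$employment_sd,
                               lower = 1)))
  # mines close in final_year: employment cannot extend past it
  n_years <- pmin(dur, config$final_year - hire_year + 1L)
  group_id <- sample.int(config$n_groups, n, replace = TRUE)
  censor_age <- pmin(hire_age + (config$admin_censor_year - hire_year),
                     config$max_age)

  worker_id <- seq_len(n)
  rows <- rep.int(worker_id, n_years)
  offset <- sequence(n_years) - 1L
  year <- hire_year[rows] + offset
  age <- hire_age[rows] + offset
  mu <- log(exposure_trend(config, year)) - config$exposure_dispersion^2 / 2
  wlm <- exp(stats::rnorm(length(rows), mu, config$exposure_dispersion))
  exposure <- data.frame(worker_id = rows,
                         group_id = group_id[rows],
                         calendar_year = year,
                         age = age,
                         period = assign_periods(year, config$period_bounds),
                         exposure_wlm = wlm)
  workers <- data.frame(worker_id = worker_id, group_id = group_id,
                        hire_year = hire_year, hire_age = hire_age,
                        duration_drawn = dur, n_years = n_years,
                        censor_age = censor_age)
  structure(list(workers = workers, exposure = exposure,
                 config = config, seed = as.integer(seed)),
            class = "miner_cohort")
}

#' @export
print.miner_cohort <- function(x, ...) {
  cat(sprintf("Synthetic miner cohort: %d workers, %d groups, %d worker-years\n",
              nrow(x$workers), x$config$n_groups, nrow(x$exposure)))
  cat(sprintf("  hire years %d-%d; periods split at %d/%d; seed %d\n",
              min(x$workers$hire_year), max(x$workers$hire_year),
              x$config$period_bounds[1L], x$config$period_bounds[2L], x$seed))
  invisible(x)
}

#' Assign exposure-assessment periods to calendar years
#'
#' Period 1 for years up to and including the first bound, period 2 between
#' the bounds (inclusive of the second), period 3 afterwards.
#'
#' @param x integer calendar years, or a data frame with a `calendar_year`
#'   column (in which case the `period` column is (re)computed).
#' @param period_bounds two increasing calendar years.
#' @return integer periods in `{1, 2, 3}`, or the data frame with its
#'   `period` column replaced.
#' @export
assign_periods <- function(x, period_bounds) {
  if (is.data.frame(x)) {
    x$period <- assign_periods(x$calendar_year, period_bounds)
    return(x)
  }
  1L + (x > period_bounds[1L]) + (x > period_bounds[2L])
}

#' Cumulative exposure in model units of 100 WLM
#'
#' Right-continuous step function of age: the exposure received during the
#' year of age `[a, a + 1)` enters cumulative exposure at age `a + 1` (end of
#' the year), so same-year exposure never predicts same-year death.  An
#' optional lag shifts the step ages further.
#'
#' @param history data frame with columns `age` (age at start of each
#'   employment year) and `exposure_wlm`, for one worker.
#' @param t ages at which to evaluate (numeric vector).
#' @param lag exposure lag in years (default 0).
#' @return cumulative exposure at each `t`, in units of 100 WLM.
#' @export
cumulative_exposure <- function(history, t, lag = 0) {
  if (nrow(history) == 0L) return(rep(0, length(t)))
  step_age <- history$age + 1 + lag
  vapply(t, function(ti) sum(history$exposure_wlm[step_age <= ti]), 0) / 100
}

#' Write / read a cohort as long-format CSV plus a JSON sidecar
#'
#' @param cohort a `miner_cohort`.
#' @param path path of the CSV file; the sidecar is written next to it with
#'   extension `.json` and records config and seed.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a
#'   `miner_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$exposure, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  meta <- list(config = unclass(cohort$config), seed = cohort$seed,
               workers = cohort$workers)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  exposure <- utils::read.csv(path)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  cfg <- meta$config
  config <- cohort_config(cfg$n_workers, cfg$n_groups, cfg$period_bounds,
                          cfg$hire_year_range, cfg$hire_age_mean,
                          cfg$hire_age_sd, cfg$hire_age_limits,
                          cfg$employment_mean, cfg$employment_sd,
                          cfg$plateau_wlm, cfg$final_wlm, cfg$final_year,
                          cfg$exposure_dispersion, cfg$admin_censor_year,
                          cfg$max_age, cfg$exposure_lag)
  structure(list(workers = as.data.frame(meta$workers), exposure = exposure,
                 config = config, seed = as.integer(meta$seed)),
            class = "miner_cohort")
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' Fields missing from the file keep their [cohort_config()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `cohort_config`.
#' @export
cohort_config_from_file <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_config, vals)
}
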