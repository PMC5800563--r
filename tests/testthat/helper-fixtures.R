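# small cohorts and fits shared across test files; everything is generated
# in code from fixed seeds

small_config <- function(n_workers = 120, ...) {
  cohort_config(n_workers = n_workers, n_groups = 4, ...)
}

small_cohort <- function(n_workers = 120, seed = 101, ...) {
  generate_cohort(small_config(n_workers, ...), seed = seed)
}

# a cohort guaranteed to span all three periods for every group
spanning_cohort <- function(n_workers = 150, seed = 202) {
  generate_cohort(cohort_config(n_workers = n_workers, n_groups = 3,
                                hire_year_range = c(1945, 1955),
                                employment_mean = 45, employment_sd = 3),
                  seed = seed)
}

# one-worker exposure history at given ages/exposures (ages at year start)
one_history <- function(exposure_wlm, first_age = 20) {
  n <- length(exposure_wlm)
  data.frame(worker_id = rep(1L, n), group_id = rep(1L, n),
             calendar_year = seq_len(n) + 1944L,
             age = first_age + seq_len(n) - 1,
             period = rep(1L, n), exposure_wlm = exposure_wlm)
}

# constant single-band baseline over the whole age range
flat_baseline <- function(rate) baseline_hazard(c(0, 110), rate)

# quick D2 (Cox) likelihood data on an error-free small cohort
quick_cox_data <- function(n_workers = 150, seed = 7, beta = 2,
                           target = 0.15) {
  coh <- small_cohort(n_workers, seed = seed)
  gen <- disease_model("D2", beta = beta)
  bl <- calibrate_baseline(baseline_hazard(), coh, gen, target)
  real <- apply_measurement_model(measurement_model("M0"), coh, seed)
  out <- simulate_cohort_outcomes(gen, bl, real, seed = seed + 1)
  list(cohort = coh, baseline = bl, realization = real, outcomes = out,
       data = ph_data(real, out, bl, "D2"))
}
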