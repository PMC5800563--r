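test_that("hazard_at reproduces the linear-EHR and log-linear forms", {
  bl <- flat_baseline(0.001)
  h <- one_history(c(50, 50), first_age = 20)   # Xcum = 1.0 after age 22
  # null effect: both families reduce to the baseline
  expect_equal(hazard_at(disease_model("D1", beta = 0), bl, h, 30), 0.001)
  expect_equal(hazard_at(disease_model("D2", beta = 0), bl, h, 30), 0.001)
  # EHR: RR = 1 + ERR, so beta = 5 at 100 WLM gives hazard 6 * lambda
  expect_equal(hazard_at(disease_model("D1", beta = 5), bl, h, 30), 0.006)
  # Cox: beta = 2 at Xcum = 0.5 gives lambda * e
  h1 <- one_history(50, first_age = 20)
  expect_equal(hazard_at(disease_model("D2", beta = 2), bl, h1, 30),
               0.001 * exp(1))
  # direct-formula oracle on a random history
  set.seed(8)
  hr <- one_history(rlnorm(10, 2, 1), first_age = 25)
  x <- cumulative_exposure(hr, 33.7)
  expect_equal(hazard_at(disease_model("D2", beta = 1.3), bl, hr, 33.7),
               0.001 * exp(1.3 * x))
  # EHR positivity violation raises
  expect_error(hazard_at(disease_model("D1", beta = -2), bl, h, 30),
               "non-positive")
})

test_that("event-time inversion matches a numerical-integration oracle", {
  qc <- quick_cox_data(n_workers = 60, seed = 19, target = 0.4)
  segs <- exposure_segments(qc$realization, qc$baseline, "true")
  model <- disease_model("D2", beta = 2)
  set.seed(33)
  for (i in sample(unique(segs$worker_id), 12)) {
    si <- segs[segs$worker_id == i, ]
    g <- exp(2 * si$x)
    hk <- qc$baseline$rates[si$k] * g
    Htot <- sum(hk * si$dur)
    E <- runif(1, 0.05, 0.95) * Htot        # guaranteed interior crossing
    inv <- invert_cumulative_hazard(hk, si$start, si$dur,
                                    max(si$start + si$dur), E)
    expect_identical(inv$event, 1L)
    # oracle: root of the trapezoid-integrated cumulative hazard
    Hfun <- function(t) {
      sum(pmin(pmax(t - si$start, 0), si$dur) * hk)
    }
    root <- uniroot(function(t) Hfun(t) - E,
                    c(min(si$start), max(si$start + si$dur)),
                    tol = 1e-12)$root
    expect_lt(abs(inv$exit_age - root), 1e-8)
  }
})

test_that("constant hazard and no exposure effect give exponential event times", {
  coh <- generate_cohort(cohort_config(n_workers = 3000, max_age = 500,
                                       admin_censor_year = 2500), seed = 55)
  bl <- baseline_hazard(c(0, 600), 0.05)
  real <- apply_measurement_model(measurement_model("M0"), coh, 1)
  out <- simulate_cohort_outcomes(disease_model("D2", beta = 0), bl, real, 66)
  tt <- out$exit_age - out$entry_age
  expect_true(all(out$event == 1L))          # censoring pushed out of reach
  expect_lt(abs(mean(tt) - 1 / 0.05), 4 * (1 / 0.05) / sqrt(3000))
  # Kaplan-Meier agrees with exp(-lambda t)
  skip_if_not_installed("survival")
  km <- survival::survfit(survival::Surv(tt, out$event) ~ 1)
  sup <- max(abs(km$surv - exp(-0.05 * km$time)))
  expect_lt(sup, 0.05)
})

test_that("zero baseline hazard always censors administratively", {
  qc <- quick_cox_data(n_workers = 40, seed = 23)
  bl0 <- flat_baseline(0)
  out <- simulate_cohort_outcomes(disease_model("D2", beta = 2), bl0,
                                  qc$realization, 5)
  expect_true(all(out$event == 0L))
  expect_equal(out$exit_age, qc$cohort$workers$censor_age)
})

test_that("event counts match the closed-form expectation under the null", {
  coh <- small_cohort(2000, seed = 77)
  bl <- flat_baseline(0.002)
  real <- apply_measurement_model(measurement_model("M0"), coh, 1)
  out <- simulate_cohort_outcomes(disease_model("D2", beta = 0), bl, real, 88)
  fu <- coh$workers$censor_age - coh$workers$hire_age
  expected <- sum(1 - exp(-0.002 * fu))
  sd_bin <- sqrt(sum((1 - exp(-0.002 * fu)) * exp(-0.002 * fu)))
  expect_lt(abs(attr(out, "n_events") - expected), 4 * sd_bin)
})

test_that("increasing the risk coefficient is monotone under common random numbers", {
  qc <- quick_cox_data(n_workers = 200, seed = 29, target = 0.1)
  bl <- qc$baseline
  out1 <- simulate_cohort_outcomes(disease_model("D2", beta = 2), bl,
                                   qc$realization, 91)
  out2 <- simulate_cohort_outcomes(disease_model("D2", beta = 4), bl,
                                   qc$realization, 91)
  # same exponential draws: nobody who failed under beta=2 survives beta=4
  expect_true(all(out2$event >= out1$event))
  expect_true(all(out2$exit_age <= out1$exit_age + 1e-12))
})

test_that("outcome generation uses the true exposure side only", {
  coh <- small_cohort(150, seed = 37)
  gen <- disease_model("D2", beta = 2)
  bl <- calibrate_baseline(baseline_hazard(), coh, gen, 0.2)
  r0 <- apply_measurement_model(measurement_model("M0"), coh, 3)
  # Berkson error with sigma2 = 0 has U = 1, so true sides coincide
  rb <- apply_measurement_model(measurement_model("M1", sigma2 = 0), coh, 3)
  out0 <- simulate_cohort_outcomes(gen, bl, r0, 44)
  outb <- simulate_cohort_outcomes(gen, bl, rb, 44)
  expect_equal(out0$exit_age, outb$exit_age)
  # classical error keeps true = reference: outcomes identical to M0
  rc <- apply_measurement_model(measurement_model("M2", sigma2 = 0.8), coh, 3)
  outc <- simulate_cohort_outcomes(gen, bl, rc, 44)
  expect_equal(out0$exit_age, outc$exit_age)
})

test_that("single-worker event times follow the closed-form inversion", {
  bl <- flat_baseline(0.05)
  m0 <- disease_model("D2", beta = 0)
  # no exposure: exit = entry + E / lambda for the seeded exponential draw
  set.seed(91); E <- rexp(1)
  out <- simulate_event_time(m0, bl, one_history(numeric(0)), 30, 90, seed = 91)
  expect_equal(out$exit_age, 30 + E / 0.05)
  expect_identical(out$event, 1L)
  # hazard too small to reach E before censoring
  out2 <- simulate_event_time(disease_model("D2", beta = 0),
                              flat_baseline(1e-9), one_history(numeric(0)),
                              30, 90, seed = 91)
  expect_identical(out2$event, 0L)
  expect_equal(out2$exit_age, 90)
  # with exposure, matches manual inversion through the exposed segments
  h <- one_history(c(200, 200), first_age = 30)
  m <- disease_model("D2", beta = 1)
  set.seed(92); E2 <- rexp(1)
  out3 <- simulate_event_time(m, bl, h, 30, 90, seed = 92)
  hk <- 0.05 * exp(c(0, 2, 4))                  # segments [30,31),[31,32),[32,90)
  H <- cumsum(hk * c(1, 1, 58))
  j <- which(H >= E2)[1]
  expected <- c(30, 31, 32)[j] + (E2 - c(0, H)[j]) / hk[j]
  expect_equal(out3$exit_age, expected)
})

test_that("segments partition follow-up with non-decreasing exposure", {
  qc <- quick_cox_data(n_workers = 80, seed = 31)
  segs <- exposure_segments(qc$realization, qc$baseline, "true")
  w <- qc$cohort$workers
  for (i in c(1, 17, 80)) {
    si <- segs[segs$worker_id == i, ]
    expect_equal(si$start[1], w$hire_age[i])
    expect_equal(sum(si$dur), w$censor_age[i] - w$hire_age[i])
    expect_true(all(diff(si$x) >= 0))
    expect_equal(abs(si$start[-1] - (si$start + si$dur)[-nrow(si)]),
                 rep(0, nrow(si) - 1L))
  }
})
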