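test_that("lognormal error fields have unit mean and degenerate zero-variance case", {
  coh <- small_cohort(400, seed = 21)
  idx <- coh$exposure
  layer0 <- error_layer("berkson", "unshared", 0)
  expect_true(all(sample_error_field(layer0, idx, 1) == 1))
  # E(U) = 1 from the -sigma2/2 log-mean; check within 3 standard errors
  for (s2 in c(0.1, 0.8)) {
    layer <- error_layer("berkson", "unshared", s2)
    u <- sample_error_field(layer, idx, 99)
    se <- sqrt((exp(s2) - 1)) / sqrt(length(u))
    expect_lt(abs(mean(u) - 1), 3 * se)
  }
})

test_that("sharing structures replicate draws over the right index sets", {
  coh <- spanning_cohort()
  idx <- coh$exposure
  # within: identical across years of one worker, distinct across workers
  u_w <- sample_error_field(error_layer("berkson", "within", 0.5), idx, 4)
  by_worker <- tapply(u_w, idx$worker_id, function(v) length(unique(v)))
  expect_true(all(by_worker == 1L))
  expect_gt(length(unique(tapply(u_w, idx$worker_id, min))), 1L)
  # between: identical across workers of a group in one year
  u_b <- sample_error_field(error_layer("classical", "between", 0.5), idx, 5)
  key <- paste(idx$group_id, idx$calendar_year)
  expect_true(all(tapply(u_b, key, function(v) length(unique(v))) == 1L))
  # both: one draw per group
  u_g <- sample_error_field(error_layer("berkson", "both", 0.5), idx, 6)
  expect_true(all(tapply(u_g, idx$group_id,
                         function(v) length(unique(v))) == 1L))
  expect_identical(length(unique(u_g)), 3L)
  # unshared: essentially all draws distinct
  u_u <- sample_error_field(error_layer("berkson", "unshared", 0.5), idx, 7)
  expect_equal(length(unique(u_u)), nrow(idx))
})

test_that("error fields are invariant to row order", {
  coh <- small_cohort(60, seed = 31)
  idx <- coh$exposure
  perm <- sample(nrow(idx))
  for (sh in c("unshared", "between", "within", "both")) {
    layer <- error_layer("berkson", sh, 0.3)
    u <- sample_error_field(layer, idx, 8)
    u_perm <- sample_error_field(layer, idx[perm, ], 8)
    expect_equal(u_perm, u[perm])
  }
})

test_that("Berkson and classical directions fix the right side", {
  coh <- small_cohort(50, seed = 41)
  n <- nrow(coh$exposure)
  ref <- coh$exposure$exposure_wlm
  u <- rep(1.2, n)
  rb <- apply_berkson(coh, u)
  expect_equal(rb$exposure$exposure_obs_wlm, ref)
  expect_equal(rb$exposure$exposure_true_wlm, ref * 1.2)
  rc <- apply_classical(coh, rep(0.8, n))
  expect_equal(rc$exposure$exposure_true_wlm, ref)
  expect_equal(rc$exposure$exposure_obs_wlm, ref * 0.8)
  # U = 1 reduces both to the identity
  r1 <- apply_berkson(coh, rep(1, n))
  expect_equal(r1$exposure$exposure_true_wlm, r1$exposure$exposure_obs_wlm)
})

test_that("conditional log-variance matches sigma2 and classical inflates variability", {
  coh <- small_cohort(600, seed = 51)
  s2 <- 0.4
  real <- apply_measurement_model(measurement_model("M1", sigma2 = s2), coh, 13)
  lr <- log(real$exposure$exposure_true_wlm) - log(real$exposure$exposure_obs_wlm)
  n <- length(lr)
  expect_lt(abs(var(lr) - s2), 4 * s2 * sqrt(2 / (n - 1)))
  realc <- apply_measurement_model(measurement_model("M2", sigma2 = s2), coh, 14)
  expect_gt(var(realc$exposure$exposure_obs_wlm),
            var(realc$exposure$exposure_true_wlm))
})

test_that("M0 is the identity and M1-M8 share one marginal error distribution", {
  coh <- small_cohort(80, seed = 61)
  r0 <- apply_measurement_model(measurement_model("M0"), coh, 1)
  expect_equal(r0$exposure$exposure_true_wlm, coh$exposure$exposure_wlm)
  expect_equal(r0$exposure$exposure_obs_wlm, coh$exposure$exposure_wlm)
  # same sigma2: pooled log-error draws agree in distribution across sharing
  coh2 <- spanning_cohort(300)
  pool <- lapply(paste0("M", c(1, 3, 5, 7)), function(id) {
    r <- apply_measurement_model(measurement_model(id, sigma2 = 0.5), coh2, 71)
    u <- log(r$exposure$exposure_true_wlm / r$exposure$exposure_obs_wlm)
    # deduplicate shared values to recover the underlying draws
    unique(round(u, 12))
  })
  for (k in 2:4) {
    ks <- suppressWarnings(ks.test(pool[[1]], pool[[k]]))
    expect_gt(ks$p.value, 1e-4)
  }
})

test_that("M9 collapses period 1 to a group constant with period-specific variances", {
  coh <- spanning_cohort(400)
  s2 <- c(0.8, 0.15, 0.01)
  m9 <- measurement_model("M9", sigma2 = s2)
  real <- apply_measurement_model(m9, coh, 17)
  ex <- real$exposure
  p1 <- ex$period == 1L
  # observed period-1 value constant within group, equal to the group mean
  for (g in unique(ex$group_id)) {
    rows <- p1 & ex$group_id == g
    expect_equal(unique(ex$exposure_obs_wlm[rows]),
                 mean(coh$exposure$exposure_wlm[rows]))
  }
  # per-period log-error variance tracks sigma2 (MC tolerance)
  lr <- log(ex$exposure_true_wlm / ex$exposure_obs_wlm)
  for (q in 1:3) {
    v <- var(lr[ex$period == q])
    n <- sum(ex$period == q)
    expect_lt(abs(v - s2[q]), 4 * s2[q] * sqrt(2 / (n - 1)) + 1e-8)
  }
  # periods 1-2 Berkson (observed untouched outside the collapse),
  # period 3 classical (true untouched)
  expect_equal(ex$exposure_obs_wlm[ex$period == 2L],
               coh$exposure$exposure_wlm[ex$period == 2L])
  expect_equal(ex$exposure_true_wlm[ex$period == 3L],
               coh$exposure$exposure_wlm[ex$period == 3L])
})

test_that("M10 shares its period-1 device error across a whole group", {
  coh <- spanning_cohort(300)
  real <- apply_measurement_model(measurement_model("M10"), coh, 19)
  ex <- real$exposure
  p1 <- ex$period == 1L
  # chi_j1 is the group constant; observed = chi * U*_j1 with one draw per
  # group, so the observed/latent ratio is a single factor per group
  for (g in unique(ex$group_id)) {
    rows <- p1 & ex$group_id == g
    chi <- mean(coh$exposure$exposure_wlm[rows])
    ratio <- ex$exposure_obs_wlm[rows] / chi
    expect_lt(diff(range(ratio)), 1e-12)
  }
  # period-2 device error shared between workers at each group-year
  p2 <- ex$period == 2L
  lat2 <- ave(coh$exposure$exposure_wlm[p2],
              paste(ex$group_id[p2], ex$calendar_year[p2]))
  ratio2 <- ex$exposure_obs_wlm[p2] / lat2
  key2 <- paste(ex$group_id[p2], ex$calendar_year[p2])
  expect_true(all(abs(tapply(ratio2, key2, function(v) diff(range(v)))) < 1e-12))
})

test_that("M11 leaves observed exposure untouched and shares a worker factor", {
  coh <- spanning_cohort(200)
  real <- apply_measurement_model(measurement_model("M11"), coh, 23)
  ex <- real$exposure
  expect_equal(ex$exposure_obs_wlm[ex$period != 3L],
               coh$exposure$exposure_wlm[ex$period != 3L])
  # total period-1 log-error variance = unshared + shared component
  lr1 <- log(ex$exposure_true_wlm / ex$exposure_obs_wlm)[ex$period == 1L]
  expect_lt(abs(var(lr1) - 0.90), 0.20)
})

test_that("total log-error variance sums layers per period", {
  m1 <- measurement_model("M1", sigma2 = 0.2)
  expect_equal(total_log_error_variance(m1)$total_sigma2, rep(0.2, 3))
  m10 <- measurement_model("M10")
  expect_equal(total_log_error_variance(m10)$total_sigma2,
               c(0.09 + 0.81, 0.03 + 0.12, 0.01))
  m0 <- measurement_model("M0")
  expect_equal(total_log_error_variance(m0)$total_sigma2, rep(0, 3))
  expect_equal(attr(total_log_error_variance(m0), "global_sigma2"), 0)
})

test_that("measurement models round-trip through config files", {
  jf <- file.path(tempdir(), "mm.json")
  writeLines('{"model": "M9", "sigma2": [0.8, 0.15, 0.01]}', jf)
  m9 <- measurement_model_from_file(jf)
  expect_identical(m9$model_id, "M9")
  expect_equal(m9$sigma2, c(0.8, 0.15, 0.01))
  skip_if_not_installed("yaml")
  yf <- file.path(tempdir(), "mm.yaml")
  writeLines(c("model: custom", "layers:",
               "  - type: berkson", "    sharing: within", "    sigma2: 0.3",
               "    periods: [1, 2]"), yf)
  mc <- measurement_model_from_file(yf)
  expect_identical(mc$layers[[1]]$sharing, "within")
  expect_equal(mc$layers[[1]]$periods, c(1L, 2L))
  unlink(c(jf, yf))
})

test_that("unknown model ids and malformed layers are rejected", {
  expect_error(measurement_model("M12"), "unknown")
  expect_error(measurement_model("M1"), "sigma2")
  expect_error(error_layer("berkson", "unshared", -0.1), ">= 0")
  expect_error(error_layer("berkson", "unshared", 0.1, periods = integer(0)),
               "periods")
  expect_error(measurement_model("custom", layers = list()), "nonempty")
})
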