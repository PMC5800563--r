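# minerr

Simulation framework for studying how **shared and unshared multiplicative
exposure measurement error** distorts risk estimation in proportional-hazards
models with time-dependent cumulative exposure — the situation of
occupational cohort studies such as historical uranium-miner cohorts, where
annual radon exposure (in working level months, WLM) was assessed by
retrospective reconstruction, then prospective group-level monitoring, then
individual dosimetry, and where the resulting errors can be Berkson or
classical and shared between workers, within workers, or both.

It is aimed at epidemiologists and biostatisticians who want to quantify, by
simulation, what happens when inference *ignores* such error.

## The models

The hazard of worker *i* at age *t* is

    h_i(t) = h0(t) · g(Xcum_i(t)),      Xcum in units of 100 WLM,

with `h0` piecewise-constant in age and `g` either the excess-hazard-ratio
(EHR) family `g = 1 + eta(x)` or the log-linear Cox family
`g = exp(eta(x))`; `eta` is linear (`beta·x`), a natural cubic spline
anchored at `eta(0) = 0`, or continuous piecewise-linear with a breakpoint
at 100 WLM (forms D1–D6).  Relative risk relates to excess hazard as
`RR = 1 + ERR`.

Measurement models M0–M11 connect true exposure `X_ij(t)` and observed
exposure `Z_ij(t)` of worker *i* in group *j* through multiplicative
log-normal errors with `log U ~ N(−σ²/2, σ²)` (so `E(U) = 1`):

| id | direction | sharing |
|----|-----------|---------|
| M0 | none (identity) | — |
| M1 / M2 | Berkson / classical | unshared |
| M3 / M4 | Berkson / classical | shared between workers (per group-year) |
| M5 / M6 | Berkson / classical | shared within workers (per worker) |
| M7 / M8 | Berkson / classical | shared both (per group) |
| M9 | period-specific, unshared | Berkson (periods 1–2), classical (period 3) |
| M10 | + shared classical device error on the observed side | per group (period 1), per group-year (period 2) |
| M11 | + shared Berkson worker-practice error on the true side | per worker, by period |

Failure times are simulated from the **true** exposure by exact inversion of
the piecewise-linear cumulative hazard; the disease models are then fitted
on the **observed** exposure by a random-walk Metropolis–Hastings sampler on
the full likelihood (centred Normal(0, 1000) prior on risk coefficients,
truncated to keep EHR hazards positive; baseline log-rates estimated
jointly).  Replicate-level posterior summaries are aggregated into relative
bias, coverage of 95% credible intervals, statistical power, pooled
intervals, exposure-response curves and DIC-based model preference.

## A worked example

Classical error shared within workers (M6), large variance, Cox generation —
the configuration the study identifies as most damaging:

```r
library(minerr)

cohort <- generate_cohort(cohort_config(n_workers = 800, n_groups = 10),
                          seed = 42)
scenario <- list(disease = "D2", measurement = "M6", beta_true = 2,
                 sigma2 = 0.8, seed = derive_seed(42, 1))
result <- run_scenario(scenario, cohort, n_replicates = 20,
                       settings = mcmc_settings(n_iter = 4000,
                                                n_burnin = 2000))
result$summary
#>   form n_replicates mean_beta_hat pooled_lower pooled_upper relative_bias
#> 1   D2           20     0.2241616    0.0849922    0.4280349    -0.8879192
#>   coverage power
#> 1        0     1
```

The generating coefficient is 2 per 100 WLM; ignoring the shared classical
error collapses the estimate to ~0.22 (relative bias ≈ −0.89) and coverage of
the 95% credible intervals to 0 — while power stays at 100%, so the analysis
would confidently report a much-too-small risk.  Under M0 (no error) the
same pipeline recovers the coefficient with coverage near 95%.

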