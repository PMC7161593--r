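# msmcumexp

Marginal structural models (MSMs) for **cumulative dichotomized exposures**
in longitudinal survey cohorts — built around the motivating case of
unhealthy sleep practices in adolescence (short sleep, social jetlag, sleep
disturbance, measured at five waves between ages 14 and 21) and substance-use
frequency in young adulthood.

The package is for epidemiologists and biostatisticians who need the full
pipeline, not just the weighted regression:

1. **Panel handling** — a long-format person-wave cohort schema with CSV
   round-trip, validation, the study's baseline exclusion rules, and
   missing-indicator coding for item non-response
   (`read_cohort()`, `apply_baseline_exclusions()`,
   `encode_missing_indicator()`).
2. **Exposure derivation** — nightly duration from bed/wake clock times
   (midnight-aware), weekly averages on the 5 + 2 night split, signed social
   jetlag under a bedtime-day convention, disturbance sum scores, and
   cumulative 0–5 exposure counts at every study cutoff
   (`derive_exposures()`, `derive_all_exposures()`).
3. **Weights** — per-wave logistic models yielding stabilized inverse
   probability-of-treatment weights, stabilized inverse
   probability-of-attrition weights for intermittent dropout with a fully
   ascertained final wave, their product, optional truncation, and balance
   diagnostics (`compute_weights()`, `balance_diagnostics()`).
4. **Effect estimation** — Model 1 (conventional covariate-adjusted
   regression), Model 2 (stabilized-weight MSM) and Model 3 (adjusted
   stabilized weights conditioning on the other practices), all with
   leverage-corrected sandwich (HC3) standard errors
   (`fit_conventional()`, `fit_msm()`, `run_table()`).
5. **Verification machinery** — a synthetic cohort generator with
   exposure→confounder feedback, informative attrition and raw-field
   emission (`simulate_cohort()`), an exact g-formula oracle
   (`counterfactual_mean()`, `oracle_slope()`), and a Monte-Carlo recovery
   harness (`recovery_study()`, `oracle_equivalence_test()`,
   `censoring_stress_test()`).

## The model

For exposure indicators $A_t \in \{0,1\}$ over waves $t = 1,\dots,5$,
baseline covariates $V$ and end-of-follow-up outcome $Y$, the MSM

$$E[Y(\bar a)] = \beta_0 + \beta_1 \sum_t a_t + \beta_2' V$$

is fitted by weighted least squares, each person weighted by

$$sw = \prod_t \frac{P(A_t = a_t \mid \bar A_{t-1}, V)}{P(A_t = a_t \mid \bar A_{t-1}, V, L_t)}
\times \prod_t \frac{P(C_t = 1 \mid V)}{P(C_t = 1 \mid V, \text{history})},$$

where $L_t$ are time-varying confounders (e.g. depression) that both drive
exposure and respond to earlier exposure, and $C_t$ indicates being observed
at wave $t$. $\beta_1$ is the change in outcome frequency per additional
wave of exposure. See the vignette
(`vignettes/cumulative-sleep-msm.Rmd`) for the full construction and the
design decisions.

## Worked example

The study data are access-restricted, so the example uses the synthetic
generator, whose causal structure (confounder feedback $\delta$, exposure
propensity on the current confounder) is known — which means the true
dose–response slope is computable exactly:

```r
library(msmcumexp)
library(dplyr)

cfg <- dgp_preset("confounded", n = 2000, seed = 42)
sim <- simulate_cohort(cfg)

ex <- derive_exposures(sim$cohort, "short_sleep", cutoff = 8)
wt <- compute_weights(sim$cohort, ex, model = 2,
                      baseline_vars = "gender", tv_vars = "depression")
weight_diagnostics(wt)
#>    mean    sd   min   max   p01   p05   p25   p50   p75   p95   p99 flagged
#> 1 0.971  1.02 0.110  22.6 0.162 0.255 0.461 0.695  1.14  2.46  5.02 FALSE

m1 <- fit_conventional(sim$cohort, ex, "cigarette",
                       baseline_vars = "gender", tv_vars = "depression")
m2 <- fit_msm(sim$cohort, ex, "cigarette", wt,
              baseline_vars = "gender", tv_vars = "depression")
bind_rows(m1, m2) %>% select(model, beta, se, ci95_low, ci95_high)
#>   model  beta     se ci95_low ci95_high
#> 1     1 0.454 0.0150    0.425     0.484
#> 2     2 0.404 0.0240    0.357     0.451

oracle_slope(cfg)$slope
#> [1] 0.3862208
```

The stabilized weights average ≈ 1, as they should. The conventional
estimate (0.454) overshoots the true marginal slope (0.386) because the
confounder trajectory is both confounder and mediator; the weighted MSM
estimate (0.404) covers it. `run_table()` produces the full
practice × cutoff × model × outcome grid in the shape of the study's
summary tables, with significance stars.

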