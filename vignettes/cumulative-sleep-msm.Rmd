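---
title: "Marginal structural models for cumulative unhealthy-sleep exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal structural models for cumulative unhealthy-sleep exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Adolescent cohort surveys measure sleep habits repeatedly (here at five
follow-up waves spanning ages 14–21) and substance-use outcomes once, at the
end of follow-up. The scientific question is a dose–response one: what is
the effect of *each additional wave* spent with an unhealthy sleep practice —
short sleep, social jetlag, or sleep disturbance — on the frequency of
cigarette or alcohol use at the final wave?

Conventional covariate-adjusted regression cannot answer this when a
time-varying covariate such as depression is simultaneously

* a **confounder** — current depression raises the probability of the current
  unhealthy practice and independently predicts later substance use — and
* a **mediator** — depression responds to the *previous* wave's sleep
  practice.

Adjusting for the depression trajectory blocks part of the causal effect;
failing to adjust leaves confounding. A marginal structural model (MSM)
resolves the dilemma by reweighting rather than conditioning: each person is
weighted by the inverse probability of the exposure sequence they actually
followed, producing a pseudo-population in which measured time-varying
confounders no longer predict exposure, and the outcome model can omit them
entirely.

## Model and weights

Write $A_t \in \{0,1\}$ for the dichotomized practice at exposure wave
$t = 1,\dots,5$ (study waves 2, 3, 6, 8, 9), $L_t$ for the time-varying
confounders, $V$ for the baseline covariates, and $Y$ for the outcome
frequency. The MSM is linear in the cumulative count,

$$E[Y(\bar a)] = \beta_0 + \beta_1 \textstyle\sum_t a_t + \beta_2' V,$$

and $\beta_1$ is the estimand: the change in outcome frequency per
additional exposure wave. It is estimated by weighted least squares with the
stabilized weight

$$sw_i = \prod_{t \,\in\, \text{obs}(i)}
  \frac{P(A_t = a_{it} \mid \bar A_{t-1}, V)}
       {P(A_t = a_{it} \mid \bar A_{t-1}, V, L_t)}
  \times
  \prod_{t \,\in\, \text{obs}(i)}
  \frac{P(C_t = 1 \mid V)}{P(C_t = 1 \mid V, \text{last } A, \text{last } L)},$$

the product of the stabilized inverse probability-of-treatment weight (IPTW)
and the stabilized inverse probability-of-attrition weight (IPAW). All
component probabilities come from per-wave logistic regressions
(`fit_exposure_models()`, `fit_attrition_models()`); waves are fitted
separately because the follow-up gaps are unequal (1, 3, 2 and 1 years).

Three analysis models are exposed:

* **Model 1** (`fit_conventional()`): unweighted regression of $Y$ on the
  cumulative count, baseline covariates, wave-1 values of the time-varying
  covariates, and the other two practices' cumulative counts. The comparison
  arm, biased under exposure–confounder feedback.
* **Model 2** (`fit_msm()` with `compute_weights(model = 2)`): the weighted
  MSM above.
* **Model 3** (`compute_weights(model = 3)`): identical except that the
  treatment-weight denominators also condition on the other two practices'
  current indicators ("adjusted stabilized weights").

### Design choices in the weight machinery

* **Numerator covariates.** The stabilization set is exposure history plus
  the baseline covariates *that the outcome model also adjusts for*
  (including the wave-1 values of the time-varying covariates, suffix
  `_w1`). A stabilized numerator may only condition on covariates present in
  the final outcome model; keeping the two sets identical is enforced by
  construction.
* **Exposure history representation.** Previous-wave indicator plus the
  cumulative count through $t-1$, not the full $2^{t-1}$ history: saturated
  history models are unstable at cohort sizes in the low thousands.
* **Intermittent attrition.** Interior waves can be missed while the final
  wave is fully ascertained (the pattern in the motivating study, whose
  interior-wave attritions were 5, 15, 353 and 295 persons with a complete
  final wave). Observation is therefore modeled per wave as a response
  process, not as monotone censoring, and each weight product runs over the
  waves actually observed. A missing wave contributes zero to the cumulative
  count — the person is retained and the attrition is handled by the IPAW
  factors, not by dropping the person.
* **Attrition-model covariates.** The denominators condition on the last
  *observed* exposure indicator and confounder values (carry-forward), which
  is exactly the information an analyst has at the time a wave is fielded.
* **Probability floor.** Predicted probabilities are clamped to
  $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$, preventing
  infinite weights from numerically saturated fits; hitting the floor logs a
  warning, not an error.
* **Truncation.** Off by default (the motivating analysis reports none);
  `compute_weights(truncation = c(1, 99))` clamps to sample percentiles and
  always retains the untruncated column.
* **Variance estimator.** All effect estimates use the HC3
  (leverage-corrected) sandwich. With untruncated stabilized weights a few
  observations carry very large weights and high leverage; the uncorrected
  HC0 sandwich understates the sampling variance there (in the package's own
  500-replicate calibration at $n = 2000$ the empirical SD of the Model-2
  slope was 0.0317 against a mean HC0 SE of 0.0269, while HC3 gave 0.0285
  and interval coverage of 0.942). Weights are probability weights: they
  enter the point estimate through `lm(..., weights = )` and the variance
  only through the sandwich.
* **Linear, not logistic.** The outcome frequencies (0–7 ordinal scale,
  treated as continuous) are modeled by weighted *linear* regression; the
  slope-per-wave scale of the motivating study's tables is linear, so the
  logistic variant is deliberately not implemented.

## Sleep-metric definitions

* Nightly duration is the clock distance from bed time to wake time,
  crossing midnight when wake $\le$ bed on the dial; equal times are
  rejected as ambiguous. Weekly average = $(5\,\text{weekday} +
  2\,\text{weekend})/7$ — the only reading of a "total hours in the week
  divided by seven" consistent with two reported schedules.
* Short sleep: weekly average strictly below 8, 7, or 6 h.
* Social jetlag: weekend bedtime minus weekday bedtime, with clock times in
  [12:00, 24:00) read as the same evening and [00:00, 12:00) as past
  midnight of the next day; without that convention a 23:00 → 01:00 pair
  would yield −22 h instead of +2 h. Dichotomized at ≥ 2, 1, or 0.5 h
  (inclusive).
* Sleep disturbance: sum of three 0–4 items, present when the sum exceeds
  zero.
* Cumulative exposure: count of exposed waves, 0–5, with missing waves
  counting as unexposed (see above); a person missing every wave has a
  missing count.
* Item non-response in categorical covariates is handled by
  `encode_missing_indicator()`: an explicit `"MISSING"` level, no rows
  dropped, observed values untouched.

## The synthetic cohort generator

The study's data are access-restricted, so verification rests on a
generator (`simulate_cohort()`) that reproduces the causal structure rather
than the data: baseline covariate $V$, confounder
$L_t = \lambda L_{t-1} + \delta A_{t-1} + N(0, \sigma_L)$ (the feedback
term $\delta$ is what makes $L$ both confounder and mediator), exposure
$A_t \sim \text{Bern}(\text{expit}(\alpha_{0t} + \alpha_a A_{t-1} +
\alpha_l L_t + \alpha_v V))$, per-wave retention depending on the last
observed state, and outcomes linear in $\sum_t A_t$ with independent noise.
Raw survey fields (bed/wake clock times to the minute, disturbance items)
are emitted so that re-deriving the indicators reproduces the latent
exposures exactly — the full pipeline, including the string-level sleep
arithmetic, is exercised in every simulation.

What the generator deliberately does **not** emulate: the survey's
multistage cluster sampling, the empirical marginal distributions of the
covariate battery, psychometric structure of the scales, or measurement
error in self-reports. Passing tests therefore demonstrate correctness of
the estimation machinery under the assumed causal structure, not fidelity
to the original cohort.

Presets (`dgp_preset()`):

* `confounded` — the reference preset ($\delta = 0.8$, $\alpha_l = 0.9$,
  full retention, continuous outcomes). Chosen so the conventional
  estimator's bias is large enough (≈ +0.08 at $n = 2000$) that the
  bias-ordering comparison is non-vacuous. Retention is complete here so
  that recovery and coverage results isolate time-varying confounding;
  attrition is studied in its own presets.
* `informative_attrition` — adds depression-driven dropout
  ($\gamma_L = -1.2$; retention ≈ 0.88/0.88/0.70/0.66 with a fully
  ascertained final wave, echoing the motivating study's pattern).
  Dropout driven by the *confounder* is the regime in which attrition
  weighting demonstrably reduces bias under the missing-as-unexposed
  cumulative coding; dropout driven purely by lagged exposure instead
  produces a selection term that partially offsets the attenuation from
  undercounted exposure, and no reweighting of complete outcomes can
  repair undercounting. (`noninformative_attrition` keeps the same rates
  with $\gamma_A = \gamma_L = 0$.)
* `binary_small` — two waves, binary confounder: the state space is small
  enough that every counterfactual mean is an exact finite sum.
* `null`, `survey` — effect-free sanity preset; schema-realism preset
  (item non-response, baseline users, missing outcomes, clamped 0–7
  outcomes).

The synthetic depression score is emitted at every exposure wave including
the last (the survey measured it only through the penultimate wave) because
the final wave's exposure model needs the current confounder.

## The g-formula oracle

`counterfactual_mean(config, regime)` computes $E[Y(\bar a)]$ by
standardization over the confounder process — the g-formula — through three
routes: a closed form for the Gaussian-confounder linear DGP (the
confounder mean evolves linearly under a fixed regime, so no integration is
needed), exact enumeration over all confounder branches for the binary
mode, and Monte-Carlo only when the 0–7 clamp makes the mean non-analytic.
`oracle_slope()` then defines the recovery target as the least-squares
slope of $E[Y(\bar a)]$ on $\sum_t a_t$ over all $2^{5}$ (or $2^2$)
regimes — exactly the estimand of the weighted regression. With feedback on,
this oracle slope *exceeds* the direct outcome coefficient $\theta_a$,
because part of the effect flows through the confounder path; recovery is
judged against the oracle, never against $\theta_a$ alone.

The enumeration route was itself checked against values frozen from an
independent brute-force script written before the package: for the
`binary_small` configuration, $E[Y(0,0)] = 0.7587530687$,
$E[Y(1,1)] = 1.3186742722$, slope $0.2799606018$.

## Verification surface and problem sizes

The test suite asserts, among others:

* metric golden values and cutoff nesting (6 ⊂ 7 ⊂ 8 h; 2 ⊂ 1 ⊂ 0.5 h) on
  10⁴ random records;
* hand-computed single-wave weights, weight mean within 0.05 of 1 at
  $n = 5000$, and per-wave confounder balance $|z| < 3$ in the
  pseudo-population (tested *given* the numerator covariates with
  cumulative-through-$t$ weights — the crude weighted association does not
  vanish under stabilized weights, since the numerator retains history
  dependence and the confounder correlates with past exposure through
  feedback);
* large-sample equivalence of the weighted estimator and the exact
  g-formula slope (gap ≤ 0.02 at $n = 200{,}000$ on `binary_small`);
* a 500-replicate recovery study at $n = 2000$: Model-2 mean slope within
  two Monte-Carlo SEs of the oracle, $|\text{bias}_2| < |\text{bias}_1|$
  with Model-1 bias ≥ 0.05, and 95%-CI coverage within [0.93, 0.97];
* attrition stress test (200 replicates): IPAW reduces $|\text{bias}|$
  under informative dropout and changes nothing under non-informative
  dropout;
* byte-identical reproduction of every artifact from a fixed master seed
  (per-replicate seeds follow the documented counter scheme in
  `rep_seed()`).

These problem sizes (500/200/100 replicates, $n = 2000$ cohorts, one
$2\times10^5$ cohort) were chosen to keep Monte-Carlo error well below each
assertion's tolerance while remaining comfortable on a single CPU.

## Known limitations

* Attrition weighting cannot repair the exposure *undercounting* that
  missing interior waves introduce into the cumulative count; it removes
  the differential-selection component only. The residual attenuation is
  visible in the stress test (both arms sit slightly below the oracle).
* The IPAW covariate set is configurable rather than canonical: the
  motivating description of the attrition model is one line, so the
  package exposes the choice instead of hard-coding a guess.
* No doubly-robust or targeted estimator, no continuous-exposure
  (density-ratio) weights, no survey-design weighting, and no
  ordinal/count outcome likelihoods.
* Exposure at the final wave is concurrent with the outcome; it is included
  in the cumulative count (as in the motivating design), which readers
  should weigh when giving the slope a causal reading wave-by-wave.
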