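test_that("stabilized weight kernel reproduces hand values", {
  expect_equal(stabilized_iptw(0.6, 0.3), 2)
  # unexposed person: complement probabilities 0.4 / 0.7
  expect_equal(stabilized_iptw(1 - 0.6, 1 - 0.3), 0.4 / 0.7)
  expect_equal(stabilized_iptw(c(0.6, 0.25), c(0.3, 0.5)), 2 * 0.5)
  m_num <- rbind(c(0.6, 0.25), c(0.5, NA))
  m_den <- rbind(c(0.3, 0.5), c(0.5, NA))
  expect_equal(stabilized_iptw(m_num, m_den), c(1, 1))
  obs <- rbind(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_equal(stabilized_iptw(rbind(c(0.6, 0.25), c(0.6, 0.25)),
                               rbind(c(0.3, 0.5), c(0.3, 0.5)),
                               observed = obs),
               c(2, 1))
})

test_that("combining and truncating weights behaves as documented", {
  iptw <- tibble::tibble(person_id = c("a", "b", "c"), iptw = c(2, 1, 0.5))
  ipaw <- tibble::tibble(person_id = c("a", "b", "c"), ipaw = c(1.5, 1, 1))
  tab <- combine_and_truncate(iptw, ipaw)
  expect_equal(tab$combined, c(3, 1, 0.5))
  expect_equal(tab$truncated, tab$combined)  # truncation off by default
  set.seed(2)
  big_i <- tibble::tibble(person_id = as.character(1:500),
                          iptw = exp(rnorm(500)))
  big_a <- tibble::tibble(person_id = as.character(1:500), ipaw = 1)
  tr <- combine_and_truncate(big_i, big_a, truncation = c(5, 95))
  q <- quantile(big_i$iptw, c(0.05, 0.95))
  expect_equal(min(tr$truncated), unname(q[1]))
  expect_equal(max(tr$truncated), unname(q[2]))
  expect_error(combine_and_truncate(iptw, ipaw, truncation = c(60, 95)),
               "truncation")
  bad <- iptw
  bad$iptw[1] <- 0
  expect_error(combine_and_truncate(bad, ipaw), "strictly positive")
  expect_error(combine_and_truncate(iptw, ipaw[1:2, ]), "different persons")
})

test_that("weight diagnostics summarize and flag deviation from one", {
  d <- weight_diagnostics(rep(1, 50))
  expect_equal(d$mean, 1)
  expect_false(d$flagged)
  expect_warning(d2 <- weight_diagnostics(rep(2, 50)), "deviates")
  expect_true(d2$flagged)
})

test_that("identical numerator and denominator covariates give unit weights", {
  cfg <- dgp_preset("confounded", n = 400, seed = 14)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  # no time-varying covariates: both model sets coincide exactly
  em <- fit_exposure_models(sim$cohort, ex, baseline_vars = "gender",
                            tv_vars = character())
  expect_equal(em$probs$p_num, em$probs$p_den, tolerance = 1e-12)
  w <- tapply(em$probs$p_num / em$probs$p_den, em$probs$person_id, prod)
  expect_equal(as.numeric(w), rep(1, length(w)), tolerance = 1e-10)
})

test_that("denominator models recover the generating propensity coefficient", {
  cfg <- dgp_preset("confounded", n = 5000, seed = 19)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  em <- fit_exposure_models(sim$cohort, ex, baseline_vars = sim_baseline,
                            tv_vars = sim_tv)
  m <- em$fits[["1"]]$denominator   # first wave: a ~ baseline + current L
  est <- coef(summary(m))["depression", ]
  expect_lt(abs(est["Estimate"] - cfg$alpha_l), 3 * est["Std. Error"])
})

test_that("a wave without exposure variation raises a separation error", {
  cfg <- dgp_preset("confounded", n = 200, seed = 4,
                    alpha0 = c(-25, -0.5, -0.3, -0.6, -0.7))
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  expect_error(fit_exposure_models(sim$cohort, ex, sim_baseline, sim_tv),
               "single level|separation")
})

test_that("attrition weights are exactly one under full retention", {
  cfg <- dgp_preset("confounded", n = 300, seed = 6)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  am <- fit_attrition_models(sim$cohort, ex, sim_baseline, sim_tv)
  expect_equal(am$ipaw$ipaw, rep(1, 300))
  expect_equal(nrow(am$probs), 4 * 300)
  expect_true(all(am$probs$c_num == 1 & am$probs$c_den == 1))
})

test_that("non-informative dropout leaves stabilized attrition weights near one", {
  cfg <- dgp_preset("noninformative_attrition", n = 2000, seed = 23)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  am <- fit_attrition_models(sim$cohort, ex, sim_baseline, sim_tv)
  expect_lt(abs(mean(am$ipaw$ipaw) - 1), 0.02)
  expect_lt(sd(am$ipaw$ipaw), 0.1)
})

test_that("inverse-probability reweighting restores the confounder distribution", {
  cfg <- dgp_preset("informative_attrition", n = 4000, seed = 29)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  am <- fit_attrition_models(sim$cohort, ex, sim_baseline, sim_tv)
  t_check <- 3L  # wave 6, where dropout is heaviest
  truth_t <- sim$truth[sim$truth$t_index == t_check, ]
  target <- mean(truth_t$L)                      # uncensored marginal
  obs <- truth_t[truth_t$observed, ]
  pr <- am$probs[am$probs$t_index == t_check & am$probs$c_obs == 1, ]
  w <- 1 / pr$c_den[match(obs$person_id, pr$person_id)]
  naive_gap <- abs(mean(obs$L) - target)
  weighted_gap <- abs(sum(w * obs$L) / sum(w) - target)
  expect_lt(weighted_gap, naive_gap)
  expect_lt(weighted_gap, 0.1)
})

test_that("pseudo-population balance removes the confounder signal", {
  cfg <- dgp_preset("confounded", n = 2000, seed = 35)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  wt <- compute_weights(sim$cohort, ex, model = 2,
                        baseline_vars = sim_baseline, tv_vars = sim_tv)
  bal <- balance_diagnostics(sim$cohort, ex, wt,
                             baseline_vars = sim_baseline, tv_vars = sim_tv)
  expect_equal(nrow(bal), 5)
  expect_true(all(abs(bal$z) < 3))
  # without weights the same regression shows strong confounding
  raw <- fit_exposure_models(sim$cohort, ex, sim_baseline, sim_tv)
  z_raw <- coef(summary(raw$fits[["3"]]$denominator))["depression", "z value"]
  expect_gt(abs(z_raw), 3)
})

test_that("model-3 weights condition on the other practices and stay stabilized", {
  cfg <- dgp_preset("confounded", n = 1500, seed = 41)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, "short_sleep", 8)
  others <- list(social_jetlag = derive_exposures(sim$cohort, "social_jetlag", 1),
                 disturbance = derive_exposures(sim$cohort, "disturbance"))
  w3 <- compute_weights(sim$cohort, ex, model = 3,
                        baseline_vars = sim_baseline, tv_vars = sim_tv,
                        other_exposures = others)
  expect_lt(abs(mean(w3$combined) - 1), 0.05)
  expect_error(compute_weights(sim$cohort, ex, model = 3,
                               baseline_vars = sim_baseline, tv_vars = sim_tv),
               "other_exposures")
})
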