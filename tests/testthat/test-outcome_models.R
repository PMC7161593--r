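make_unit_weights <- function(ids, model = 2L) {
  tab <- combine_and_truncate(tibble::tibble(person_id = ids, iptw = 1),
                              tibble::tibble(person_id = ids, ipaw = 1))
  attr(tab, "model") <- model
  tab
}

test_that("unit weights reproduce the unweighted fit exactly", {
  cfg <- dgp_preset("confounded", n = 400, seed = 50)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  ids <- unique(ex$person_id)
  wt <- make_unit_weights(ids)
  msm <- fit_msm(sim$cohort, ex, "cigarette", wt, sim_baseline, sim_tv)
  # independent assembly of the same regression
  w9 <- sim$cohort[sim$cohort$wave == 9, ]
  w1 <- sim$cohort[sim$cohort$wave == 1, ]
  d <- data.frame(y = w9$outcome_cig[match(ids, w9$person_id)],
                  cumulative = ex$cumulative[match(ids, ex$person_id)],
                  gender = w1$gender[match(ids, w1$person_id)],
                  depression_w1 = w1$depression[match(ids, w1$person_id)])
  ref <- lm(y ~ cumulative + gender + depression_w1, data = d)
  expect_equal(msm$beta, unname(coef(ref)["cumulative"]), tolerance = 1e-10)
})

test_that("integer weights equal replicated unweighted rows (point estimates)", {
  cfg <- dgp_preset("confounded", n = 150, seed = 51)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  ids <- unique(ex$person_id)
  set.seed(1)
  reps <- sample(1:3, length(ids), replace = TRUE)
  wt <- combine_and_truncate(tibble::tibble(person_id = ids, iptw = reps),
                             tibble::tibble(person_id = ids, ipaw = 1))
  msm <- fit_msm(sim$cohort, ex, "cigarette", wt, sim_baseline, sim_tv)
  w9 <- sim$cohort[sim$cohort$wave == 9, ]
  w1 <- sim$cohort[sim$cohort$wave == 1, ]
  d <- data.frame(y = w9$outcome_cig[match(ids, w9$person_id)],
                  cumulative = ex$cumulative[match(ids, ex$person_id)],
                  gender = w1$gender[match(ids, w1$person_id)],
                  depression_w1 = w1$depression[match(ids, w1$person_id)])
  d_rep <- d[rep(seq_len(nrow(d)), reps), ]
  ref <- lm(y ~ cumulative + gender + depression_w1, data = d_rep)
  expect_equal(msm$beta, unname(coef(ref)["cumulative"]), tolerance = 1e-10)
})

test_that("effect rows carry a consistent robust confidence interval", {
  cfg <- dgp_preset("confounded", n = 500, seed = 52)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  est <- fit_conventional(sim$cohort, ex, "cigarette", sim_baseline, sim_tv)
  expect_equal(est$ci95_low, est$beta - 1.96 * est$se)
  expect_equal(est$ci95_high, est$beta + 1.96 * est$se)
  expect_true(est$ci95_low <= est$beta && est$beta <= est$ci95_high)
  expect_equal(est$model, 1L)
  expect_equal(est$n_used, 500L)
})

test_that("null effect without confounding is recovered by both models", {
  # alpha_l = 0 removes confounding entirely; theta_a = delta = 0 removes
  # the causal effect
  cfg <- dgp_preset("null", n = 2000, seed = 53, alpha_l = 0)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  m1 <- fit_conventional(sim$cohort, ex, "cigarette", sim_baseline, sim_tv)
  expect_lt(abs(m1$beta), 3 * m1$se)
  wt <- compute_weights(sim$cohort, ex, 2, sim_baseline, sim_tv)
  m2 <- fit_msm(sim$cohort, ex, "cigarette", wt, sim_baseline, sim_tv)
  expect_lt(abs(m2$beta), 3 * m2$se)
})

test_that("aliased design columns raise a rank-deficiency error", {
  cfg <- dgp_preset("confounded", n = 200, seed = 54)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  co$gender_copy <- co$gender
  ex <- derive_exposures(co, cfg$practice, cfg$cutoff)
  expect_error(fit_conventional(co, ex, "cigarette",
                                c("gender", "gender_copy"), sim_tv),
               "aliased.*gender_copy")
})

test_that("non-positive weights and uncovered persons are refused", {
  cfg <- dgp_preset("confounded", n = 100, seed = 55)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, cfg$practice, cfg$cutoff)
  ids <- unique(ex$person_id)
  wt <- make_unit_weights(ids)
  wt$combined[1] <- -1
  expect_error(fit_msm(sim$cohort, ex, "cigarette", wt, sim_baseline, sim_tv),
               "non-positive")
  wt2 <- make_unit_weights(ids[-1])
  expect_error(fit_msm(sim$cohort, ex, "cigarette", wt2, sim_baseline, sim_tv),
               "does not cover")
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(msmcumexp:::significance_stars(c(0.2, 0.04, 0.004, 0.0004)),
               c("", "*", "**", "***"))
})

test_that("the full practice-by-model grid produces the study-table shape", {
  cfg <- dgp_preset("confounded", n = 800, seed = 56)
  sim <- simulate_cohort(cfg)
  tab <- run_table(sim$cohort, models = c(1, 2, 3),
                   baseline_vars = sim_baseline, tv_vars = sim_tv)
  # 7 practice-cutoff combinations x 3 models x 2 outcomes
  expect_equal(nrow(tab), 7 * 3 * 2)
  expect_setequal(unique(tab$model), c(1L, 2L, 3L))
  expect_true(all(c("beta", "ci95_low", "ci95_high", "stars") %in% names(tab)))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$beta, tab$beta)
  expect_equal(nrow(back), nrow(tab))
})

test_that("models 2 and 3 coincide when the other practices are causally inert", {
  cfg <- dgp_preset("confounded", n = 2000, seed = 57)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, "short_sleep", 8)
  others <- list(social_jetlag = derive_exposures(sim$cohort, "social_jetlag", 1),
                 disturbance = derive_exposures(sim$cohort, "disturbance"))
  w2 <- compute_weights(sim$cohort, ex, 2, sim_baseline, sim_tv)
  w3 <- compute_weights(sim$cohort, ex, 3, sim_baseline, sim_tv,
                        other_exposures = others)
  m2 <- fit_msm(sim$cohort, ex, "cigarette", w2, sim_baseline, sim_tv)
  m3 <- fit_msm(sim$cohort, ex, "cigarette", w3, sim_baseline, sim_tv)
  expect_equal(m3$model, 3L)
  expect_lt(abs(m2$beta - m3$beta), 0.05)
})
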