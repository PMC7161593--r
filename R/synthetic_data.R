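#' Configure the synthetic cohort data-generating process
#'
#' The generator follows the causal structure of the study design: a binary
#' baseline covariate V (reported as gender), a time-varying confounder L
#' (reported as the depression score) that responds to the previous wave's
#' exposure, a binary unhealthy-sleep exposure A whose propensity depends on
#' its own history and the current confounder, wave-specific attrition that
#' may depend on the last observed state, and continuous end-of-follow-up
#' substance-use frequencies linear in cumulative exposure:
#'
#' \deqn{L_t = \lambda L_{t-1} + \delta A_{t-1} + N(0, \sigma_L)}
#' \deqn{A_t \sim Bern(expit(\alpha_{0t} + \alpha_a A_{t-1} + \alpha_l L_t + \alpha_v V))}
#' \deqn{Y = \theta_0 + \theta_a \sum_t A_t + \theta_l \bar L + \theta_v V + N(0, \sigma_Y)}
#'
#' With `l_type = "binary"` the confounder is instead Bernoulli with
#' \eqn{P(L_t = 1) = expit(\kappa_0 + \kappa_l L_{t-1} + \delta A_{t-1})},
#' which keeps the state space finite so counterfactual means can be
#' enumerated exactly (see [counterfactual_mean]).
#'
#' When `delta != 0` and `alpha_l != 0` the confounder is simultaneously a
#' confounder and a mediator -- the structure under which conventional
#' covariate-adjusted regression is biased and the weighted (MSM) analysis
#' is not.
#'
#' @param n Number of persons.
#' @param t_max Number of exposure waves (default 5, waves 2/3/6/8/9).
#' @param seed Integer seed; every run with the same config is
#'   byte-identical.
#' @param p_v Baseline covariate prevalence.
#' @param l_type `"gaussian"` (default) or `"binary"` confounder.
#' @param l_mu0,l_sd0 Mean and SD of the baseline (wave-1) confounder
#'   (gaussian mode).
#' @param l_sd Innovation SD of the confounder process (gaussian mode).
#' @param l_p0 Baseline confounder prevalence (binary mode).
#' @param kappa0,kappa_l Binary-mode confounder model intercept and
#'   autoregression.
#' @param lambda Confounder autocorrelation (gaussian mode).
#' @param delta Feedback coefficient of the previous exposure on the
#'   current confounder.
#' @param alpha0 Per-wave exposure-model intercepts (recycled to `t_max`).
#' @param alpha_a,alpha_l,alpha_v Exposure-model coefficients on the lagged
#'   exposure, current confounder and baseline covariate.
#' @param theta0,theta_a,theta_l,theta_v,sigma_y Outcome-model intercept,
#'   slope per exposure wave, confounder-mean effect, baseline effect and
#'   noise SD. Both outcomes (cigarette, alcohol) share the structure with
#'   independent noise.
#' @param gamma0 Per-wave retention intercepts for the interior waves
#'   (recycled to `t_max - 1`), or `NULL` for full retention. The final
#'   wave is always ascertained, matching the study's complete wave-9
#'   follow-up.
#' @param gamma_a,gamma_l Retention-model coefficients on the last observed
#'   exposure and confounder; zero makes attrition non-informative.
#' @param miss_rate Per-record probability of item non-response in each
#'   field group (sleep times, disturbance items, confounder) at observed
#'   waves.
#' @param baseline_use_rate Fraction of persons flagged as wave-1 substance
#'   users (targets of [apply_baseline_exclusions]).
#' @param outcome_miss_rate Fraction of persons with a missing wave-9
#'   outcome.
#' @param practice,cutoff Which dichotomized sleep practice the latent
#'   exposure is emitted as (see [derive_exposures]).
#' @param clamp_outcome Round and clamp outcomes to the 0--7 survey
#'   frequency scale. Off by default: clamping makes the true slope
#'   non-analytic, so the continuous scale is used for recovery studies.
#' @return A `dgp_config` list.
#' @seealso [dgp_preset] for the named presets used in the recovery study.
#' @export
dgp_config <- function(n = 2000, t_max = 5, seed = 1,
                       p_v = 0.5,
                       l_type = c("gaussian", "binary"),
                       l_mu0 = 0, l_sd0 = 1, l_sd = 0.8,
                       l_p0 = 0.4, kappa0 = -0.3, kappa_l = 0.8,
                       lambda = 0.6, delta = 0.8,
                       alpha0 = c(-0.8, -0.5, -0.3, -0.6, -0.7),
                       alpha_a = 0.6, alpha_l = 0.9, alpha_v = 0.3,
                       theta0 = 0.5, theta_a = 0.3, theta_l = 0.4,
                       theta_v = 0.2, sigma_y = 1,
                       gamma0 = NULL, gamma_a = 0, gamma_l = 0,
                       miss_rate = 0, baseline_use_rate = 0,
                       outcome_miss_rate = 0,
                       practice = "short_sleep", cutoff = 8,
                       clamp_outcome = FALSE) {
  l_type <- match.arg(l_type)
  stopifnot(n >= 1, t_max >= 1, t_max <= 5, sigma_y > 0,
            miss_rate >= 0, miss_rate < 1)
  alpha0 <- rep_len(alpha0, t_max)
  if (!is.null(gamma0)) gamma0 <- rep_len(gamma0, max(t_max - 1L, 1L))
  cfg <- list(n = as.integer(n), t_max = as.integer(t_max), seed = as.integer(seed),
              p_v = p_v, l_type = l_type,
              l_mu0 = l_mu0, l_sd0 = l_sd0, l_sd = l_sd,
              l_p0 = l_p0, kappa0 = kappa0, kappa_l = kappa_l,
              lambda = lambda, delta = delta,
              alpha0 = alpha0, alpha_a = alpha_a, alpha_l = alpha_l,
              alpha_v = alpha_v,
              theta0 = theta0, theta_a = theta_a, theta_l = theta_l,
              theta_v = theta_v, sigma_y = sigma_y,
              gamma0 = gamma0, gamma_a = gamma_a, gamma_l = gamma_l,
              miss_rate = miss_rate, baseline_use_rate = baseline_use_rate,
              outcome_miss_rate = outcome_miss_rate,
              practice = practice, cutoff = cutoff,
              clamp_outcome = clamp_outcome)
  structure(cfg, class = "dgp_config")
}

#' Named data-generating presets
#'
#' * `"confounded"`: the reference preset for recovery studies --
#'   exposure-confounder feedback on (`delta = 0.8`, `alpha_l = 0.9`), full
#'   retention, continuous outcomes. Constructed so the conventional
#'   regression carries visible time-varying-confounding bias while the
#'   correctly specified weighted analysis does not.
#' * `"null"`: no causal effect and no feedback (`theta_a = 0`,
#'   `delta = 0`); both analyses should recover zero.
#' * `"informative_attrition"`: the confounded structure plus interior-wave
#'   dropout driven by the last observed confounder value (depressed
#'   adolescents drop out; attrition thereby also depends on earlier
#'   exposure through the feedback path), heavier at the later interior
#'   waves, echoing the study's attrition pattern.
#' * `"noninformative_attrition"`: same dropout rates but independent of
#'   history.
#' * `"binary_small"`: a two-wave binary-confounder instance whose
#'   counterfactual means are exactly enumerable; used to check the
#'   weighted estimator against the g-formula.
#' * `"survey"`: the confounded structure with survey-realism switches on
#'   (item non-response, wave-1 substance users, missing outcomes, clamped
#'   0--7 outcomes) for exercising the data-handling layer.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [dgp_config] (e.g. `n`, `seed`).
#' @return A `dgp_config`.
#' @export
dgp_preset <- function(preset = c("confounded", "null", "informative_attrition",
                                  "noninformative_attrition", "binary_small",
                                  "survey"),
                       ...) {
  preset <- match.arg(preset)
  base <- switch(
    preset,
    confounded = list(),
    null = list(theta_a = 0, delta = 0),
    informative_attrition = list(gamma0 = c(2.5, 2.5, 1.6, 1.6),
                                 gamma_a = 0, gamma_l = -1.2),
    noninformative_attrition = list(gamma0 = c(2.5, 2.5, 1.6, 1.6),
                                    gamma_a = 0, gamma_l = 0),
    binary_small = list(t_max = 2, l_type = "binary",
                        l_p0 = 0.4, kappa0 = -0.3, kappa_l = 0.8,
                        delta = 0.9,
                        alpha0 = c(-0.5, -0.5), alpha_a = 0.5,
                        alpha_l = 1.0, alpha_v = 0.4,
                        theta0 = 0.3, theta_a = 0.25, theta_l = 0.6,
                        theta_v = 0.3, sigma_y = 1),
    survey = list(miss_rate = 0.07, baseline_use_rate = 0.1,
                  outcome_miss_rate = 0.05, clamp_outcome = TRUE,
                  gamma0 = c(4.5, 4.0, 1.8, 1.8),
                  gamma_a = -0.3, gamma_l = -0.3)
  )
  do.call(dgp_config, utils::modifyList(base, list(...)))
}

expit <- function(x) 1 / (1 + exp(-x))

#' Emit raw survey sleep fields consistent with latent exposure indicators
#'
#' Inverse of the sleep-metric derivations: given latent 0/1 indicators for
#' one practice at one wave, draws bed/wake clock times and disturbance
#' items such that re-deriving the indicator from the emitted fields
#' reproduces the latent value exactly. Emitted clock times are rounded to
#' whole minutes with a safety margin at the cutoff so rounding can never
#' flip an indicator.
#'
#' @param a Integer 0/1 vector of latent indicators.
#' @param practice,cutoff Practice and threshold being emitted.
#' @return A tibble with columns `weekday_bed`, `weekday_wake`,
#'   `weekend_bed`, `weekend_wake` ("HH:MM"), `dist_insomnia`,
#'   `dist_early_waking`, `dist_night_waking`.
#' @export
emit_raw_sleep <- function(a, practice = c("short_sleep", "social_jetlag",
                                           "disturbance"),
                           cutoff = 8) {
  practice <- match.arg(practice)
  n <- length(a)
  margin <- 0.1  # hours; > 1-minute rounding error
  if (practice == "short_sleep") {
    lo_exp <- max(4.5, cutoff - 2.5)
    if (lo_exp >= cutoff - margin) stop("infeasible emission bounds", call. = FALSE)
    dur <- ifelse(a == 1,
                  runif(n, lo_exp, cutoff - margin),
                  runif(n, cutoff + margin, cutoff + 1.5))
    dur_min <- round(dur * 60)
    wd_bed <- 1290L + sample.int(150L, n, replace = TRUE)  # 21:31-00:00
    shift <- round(runif(n, -0.5, 2.5) * 60)
    we_bed <- wd_bed + shift
    wd_wake <- (wd_bed + dur_min) %% 1440L
    we_wake <- (we_bed + dur_min) %% 1440L
    out <- tibble::tibble(weekday_bed = format_clock(wd_bed %% 1440L),
                          weekday_wake = format_clock(wd_wake),
                          weekend_bed = format_clock(we_bed %% 1440L),
                          weekend_wake = format_clock(we_wake))
    items <- incidental_items(n)
  } else if (practice == "social_jetlag") {
    if (cutoff <= -1 + margin) stop("infeasible emission bounds", call. = FALSE)
    jl <- ifelse(a == 1,
                 runif(n, cutoff + margin, cutoff + 2),
                 runif(n, -1, cutoff - margin))
    jl_min <- round(jl * 60)
    wd_bed <- 1260L + sample.int(180L, n, replace = TRUE)  # 21:01-24:00
    we_bed <- wd_bed + jl_min
    wd_dur <- round(runif(n, 6.5, 9) * 60)
    we_dur <- round(runif(n, 6.5, 9) * 60)
    out <- tibble::tibble(weekday_bed = format_clock(wd_bed %% 1440L),
                          weekday_wake = format_clock((wd_bed + wd_dur) %% 1440L),
                          weekend_bed = format_clock(we_bed %% 1440L),
                          weekend_wake = format_clock((we_bed + we_dur) %% 1440L))
    items <- incidental_items(n)
  } else {
    i1 <- ifelse(a == 1, 1L + rbinom(n, 3, 0.25), 0L)
    i2 <- ifelse(a == 1, rbinom(n, 2, 0.3), 0L)
    i3 <- ifelse(a == 1, rbinom(n, 2, 0.3), 0L)
    items <- tibble::tibble(dist_insomnia = as.integer(i1),
                            dist_early_waking = as.integer(i2),
                            dist_night_waking = as.integer(i3))
    wd_bed <- 1290L + sample.int(150L, n, replace = TRUE)
    shift <- round(runif(n, -0.5, 2.5) * 60)
    dur <- round(runif(n, 6.5, 9.5) * 60)
    out <- tibble::tibble(weekday_bed = format_clock(wd_bed %% 1440L),
                          weekday_wake = format_clock((wd_bed + dur) %% 1440L),
                          weekend_bed = format_clock((wd_bed + shift) %% 1440L),
                          weekend_wake = format_clock((wd_bed + shift + dur) %% 1440L))
  }
  dplyr::bind_cols(out, items)
}

# Low-severity disturbance items that never sum past the relevant margins:
# for practices other than "disturbance" the items are free covariates.
incidental_items <- function(n) {
  tibble::tibble(dist_insomnia = rbinom(n, 2, 0.2),
                 dist_early_waking = rbinom(n, 2, 0.15),
                 dist_night_waking = rbinom(n, 2, 0.15))
}

#' Simulate a synthetic cohort
#'
#' Sequentially generates baseline covariates, confounder and exposure
#' trajectories with feedback, attrition, outcomes and the raw survey
#' fields (bed/wake times, disturbance items) from which the latent
#' exposures can be re-derived, per the model in [dgp_config].
#'
#' @param config A `dgp_config`.
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return A list of class `sim_cohort` with elements:
#'   * `cohort`: a long-format cohort tibble in the canonical schema;
#'   * `truth`: a person-wave tibble of the latent `V`, `L`, `A`,
#'     `observed`, plus person-level `sum_a`, `l_bar`, `y_cig`, `y_alc`;
#'   * `config`: the configuration used.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "dgp_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n
  t_max <- config$t_max
  waves <- wave_order()
  ew <- exposure_waves()[seq_len(t_max)]

  v <- rbinom(n, 1, config$p_v)
  if (config$l_type == "gaussian") {
    l0 <- rnorm(n, config$l_mu0, config$l_sd0)
  } else {
    l0 <- rbinom(n, 1, config$l_p0)
  }
  L <- matrix(NA_real_, n, t_max)
  A <- matrix(NA_integer_, n, t_max)
  C <- matrix(TRUE, n, t_max)
  a_prev <- rep(0L, n)
  l_prev <- l0
  last_a_obs <- rep(0L, n)
  last_l_obs <- l0
  for (t in seq_len(t_max)) {
    if (config$l_type == "gaussian") {
      lt <- config$lambda * l_prev + config$delta * a_prev +
        rnorm(n, 0, config$l_sd)
    } else {
      lt <- rbinom(n, 1, expit(config$kappa0 + config$kappa_l * l_prev +
                                 config$delta * a_prev))
    }
    at <- rbinom(n, 1, expit(config$alpha0[t] + config$alpha_a * a_prev +
                               config$alpha_l * lt + config$alpha_v * v))
    L[, t] <- lt
    A[, t] <- at
    if (t < t_max && !is.null(config$gamma0)) {
      # retention depends on the last *observed* state, which is what an
      # analyst can condition on; the final wave is always ascertained
      p_obs <- expit(config$gamma0[t] + config$gamma_a * last_a_obs +
                       config$gamma_l * last_l_obs)
      C[, t] <- rbinom(n, 1, p_obs) == 1
    }
    obs_t <- C[, t]
    last_a_obs[obs_t] <- at[obs_t]
    last_l_obs[obs_t] <- lt[obs_t]
    a_prev <- at
    l_prev <- lt
  }
  sum_a <- rowSums(A)
  l_bar <- rowMeans(L)
  y_cig <- config$theta0 + config$theta_a * sum_a + config$theta_l * l_bar +
    config$theta_v * v + rnorm(n, 0, config$sigma_y)
  y_alc <- config$theta0 + config$theta_a * sum_a + config$theta_l * l_bar +
    config$theta_v * v + rnorm(n, 0, config$sigma_y)
  if (config$clamp_outcome) {
    y_cig <- pmin(pmax(round(y_cig), 0), 7)
    y_alc <- pmin(pmax(round(y_alc), 0), 7)
  }

  person_id <- sprintf("p%05d", seq_len(n))

  # baseline (time-invariant) survey covariates; gender carries V
  ti <- tibble::tibble(
    person_id = person_id,
    gender = ifelse(v == 1, "male", "female"),
    urbanization = sample(c("city", "suburban", "rural"), n, TRUE,
                          prob = c(0.38, 0.38, 0.24)),
    township = sample(c("core_city", "general_city", "emerging_town",
                        "general_town", "aging_town"), n, TRUE,
                      prob = c(0.48, 0.28, 0.13, 0.08, 0.03)),
    puberty = sample(c("early", "on_time", "late"), n, TRUE,
                     prob = c(0.07, 0.35, 0.58)),
    expect_college = sample(c("yes", "no"), n, TRUE, prob = c(0.75, 0.25)),
    father_ethnicity = sample(c("islander", "hakka", "mainlander", "other"),
                              n, TRUE, prob = c(0.78, 0.08, 0.12, 0.02))
  )
  baseline_user <- rbinom(n, 1, config$baseline_use_rate) == 1
  outcome_missing <- rbinom(n, 1, config$outcome_miss_rate) == 1

  empty_raw <- tibble::tibble(weekday_bed = NA_character_,
                              weekday_wake = NA_character_,
                              weekend_bed = NA_character_,
                              weekend_wake = NA_character_,
                              dist_insomnia = NA_integer_,
                              dist_early_waking = NA_integer_,
                              dist_night_waking = NA_integer_)

  rows <- vector("list", length(waves))
  miss_log <- c(sleep = 0L, items = 0L, depression = 0L)
  for (wi in seq_along(waves)) {
    w <- waves[wi]
    r <- tibble::tibble(person_id = person_id, wave = w)
    r <- dplyr::bind_cols(r, empty_raw[rep(1L, n), ])
    r$outcome_cig <- NA_real_
    r$outcome_alc <- NA_real_
    r$depression <- NA_real_
    r$self_rated_health <- NA_character_
    r$academic_rank <- NA_character_
    r$cram_school <- NA_character_
    r$self_substance <- NA_character_
    r$peer_substance <- NA_character_
    r$live_parents <- NA_character_
    r$job <- NA_character_
    if (w == 1L) {
      r$observed <- TRUE
      r$depression <- l0
      r$self_rated_health <- sample(c("good", "bad"), n, TRUE, prob = c(0.86, 0.14))
      r$academic_rank <- sample(c("top5", "other"), n, TRUE, prob = c(0.17, 0.83))
      r$cram_school <- sample(c("yes", "no"), n, TRUE, prob = c(0.67, 0.33))
      r$live_parents <- sample(c("yes", "no"), n, TRUE, prob = c(0.89, 0.11))
      r$self_substance <- ifelse(baseline_user, "yes", "no")
    } else {
      t <- match(w, ew)
      if (is.na(t)) {
        # waves beyond a short follow-up (t_max < 5): present but no
        # exposure measurement
        r$observed <- TRUE
      } else {
        obs <- C[, t]
        r$observed <- obs
        raw <- emit_raw_sleep(A[, t], config$practice, config$cutoff)
        r[obs, names(raw)] <- raw[obs, ]
        r$depression[obs] <- L[obs, t]
        r$self_rated_health[obs] <- sample(c("good", "bad"), sum(obs), TRUE,
                                           prob = c(0.9, 0.1))
        r$self_substance[obs] <- sample(c("yes", "no"), sum(obs), TRUE,
                                        prob = c(0.15, 0.85))
        r$peer_substance[obs] <- sample(c("yes", "no"), sum(obs), TRUE,
                                        prob = c(0.25, 0.75))
        if (config$miss_rate > 0) {
          sleep_cols <- c("weekday_bed", "weekday_wake", "weekend_bed",
                          "weekend_wake")
          item_cols <- c("dist_insomnia", "dist_early_waking",
                         "dist_night_waking")
          m1 <- obs & rbinom(n, 1, config$miss_rate) == 1
          m2 <- obs & rbinom(n, 1, config$miss_rate) == 1
          m3 <- obs & rbinom(n, 1, config$miss_rate) == 1
          r[m1, sleep_cols] <- NA
          r[m2, item_cols] <- NA
          r$depression[m3] <- NA
          miss_log <- miss_log + c(sleep = sum(m1), items = sum(m2),
                                   depression = sum(m3))
        }
      }
      if (w == 9L) {
        r$outcome_cig <- ifelse(outcome_missing, NA_real_, y_cig)
        r$outcome_alc <- ifelse(outcome_missing, NA_real_, y_alc)
      }
    }
    rows[[wi]] <- r
  }
  cohort <- dplyr::bind_rows(rows)
  cohort <- dplyr::left_join(cohort, ti, by = "person_id")
  cohort <- dplyr::arrange(cohort, person_id, match(wave, waves))
  core_first <- c(cohort_core_columns(),
                  setdiff(names(cohort), cohort_core_columns()))
  cohort <- cohort[, core_first]
  if (config$clamp_outcome) {
    cohort$outcome_cig <- as.integer(cohort$outcome_cig)
    cohort$outcome_alc <- as.integer(cohort$outcome_alc)
  }
  cohort <- as_cohort(cohort)
  attr(cohort, "miss_log") <- miss_log

  truth_waves <- tibble::tibble(
    person_id = rep(person_id, t_max),
    t_index = rep(seq_len(t_max), each = n),
    wave = rep(ew, each = n),
    V = rep(v, t_max),
    L = as.vector(L),
    A = as.vector(A),
    observed = as.vector(C)
  )
  truth_person <- tibble::tibble(person_id = person_id, V = v, l0 = l0,
                                 sum_a = sum_a, l_bar = l_bar,
                                 y_cig = y_cig, y_alc = y_alc)
  structure(list(cohort = cohort,
                 truth = truth_waves,
                 truth_person = truth_person,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort>", x$config$n, "persons,", x$config$t_max,
      "exposure waves, practice", x$config$practice,
      sprintf("(cutoff %s), seed %d\n", x$config$cutoff, x$config$seed))
  invisible(x)
}
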