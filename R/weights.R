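#' Fit per-wave exposure propensity models
#'
#' For each exposure wave, fits two logistic regressions for the observed
#' exposure indicator: a *denominator* model conditioning on exposure
#' history (previous indicator and cumulative count), the baseline
#' covariates and the current time-varying covariates (plus, for the
#' adjusted Model-3 weights, the other practices' current indicators), and
#' a *numerator* (stabilization) model conditioning on history and baseline
#' covariates only. The numerator covariate set is a subset of the
#' denominator's, the standard stabilized-weight construction.
#'
#' Waves are fitted separately (not pooled) because the survey's follow-up
#' gaps are unequal. Models are fitted on records observed at that wave
#' with a non-missing indicator. Predicted probabilities are clamped to
#' `[eps, 1 - eps]`.
#'
#' @param cohort A cohort tibble.
#' @param exposure A derived exposure tibble from [derive_exposures].
#' @param baseline_vars Time-invariant covariate columns (numerator and
#'   denominator).
#' @param tv_vars Time-varying covariate columns; their wave-1 values join
#'   the baseline set (suffix `_w1`), their current values enter the
#'   denominator only.
#' @param other_exposures Named list of other practices' exposure tibbles
#'   whose current-wave indicators are added to the denominator (Model 3);
#'   `NULL` for Model 2.
#' @param eps Probability floor/ceiling.
#' @return A list of class `exposure_models`: `probs` (tibble of
#'   `person_id`, `t_index`, `p_num`, `p_den` -- probabilities of the
#'   *observed* exposure value), `fits` (per-wave model pairs), `waves`
#'   (fitted wave indices).
#' @export
fit_exposure_models <- function(cohort, exposure,
                                baseline_vars = character(),
                                tv_vars = character(),
                                other_exposures = NULL,
                                eps = 1e-6) {
  base <- baseline_frame(cohort, baseline_vars, tv_vars)
  fr <- exposure_frame(cohort, exposure, tv_vars)
  if (!is.null(other_exposures)) fr <- add_other_practices(fr, other_exposures)
  fr <- dplyr::left_join(fr, base, by = "person_id")
  base_terms <- setdiff(names(base), "person_id")
  other_terms <- if (is.null(other_exposures)) character() else
    paste0("other_", names(other_exposures))
  t_fit <- sort(unique(fr$t_index[!is.na(fr$a) & fr$observed]))
  fits <- list()
  probs <- list()
  for (t in t_fit) {
    d <- fr[fr$t_index == t & fr$observed & !is.na(fr$a), , drop = FALSE]
    hist_terms <- if (t == 1) character() else if (t == 2) "a_lag" else
      c("a_lag", "cum_lag")
    num_terms <- c(hist_terms, base_terms)
    den_terms <- c(hist_terms, base_terms, tv_vars, other_terms)
    used <- unique(c("a", den_terms))
    cc <- complete.cases(d[used])
    d <- drop_unused_factor_levels(d[cc, , drop = FALSE])
    if (nrow(d) == 0) stop("no usable records at exposure wave ", t, call. = FALSE)
    if (length(unique(d$a)) < 2) {
      stop("exposure has a single level at wave ", t,
           ": cannot fit propensity model (separation)", call. = FALSE)
    }
    f_num <- reformulate(if (length(num_terms)) num_terms else "1", response = "a")
    f_den <- reformulate(if (length(den_terms)) den_terms else "1", response = "a")
    m_num <- glm(f_num, data = d, family = binomial())
    m_den <- glm(f_den, data = d, family = binomial())
    check_separation(m_den, t)
    p1_num <- clamp_prob(predict(m_num, type = "response"), eps)
    p1_den <- clamp_prob(predict(m_den, type = "response"), eps)
    probs[[length(probs) + 1L]] <- tibble::tibble(
      person_id = d$person_id, t_index = t, a = d$a,
      p_num = ifelse(d$a == 1, p1_num, 1 - p1_num),
      p_den = ifelse(d$a == 1, p1_den, 1 - p1_den))
    fits[[as.character(t)]] <- list(numerator = m_num, denominator = m_den)
  }
  structure(list(probs = dplyr::bind_rows(probs), fits = fits, waves = t_fit,
                 eps = eps),
            class = "exposure_models")
}

check_separation <- function(model, t) {
  co <- coef(model)
  co <- co[!is.na(co)]
  big <- abs(co) > 30
  if (any(big)) {
    stop("possible perfect separation at wave ", t, " (covariate ",
         names(co)[which.max(abs(co))], ")", call. = FALSE)
  }
}

clamp_prob <- function(p, eps) {
  hit <- sum(p < eps | p > 1 - eps)
  if (hit > 0) {
    warning(hit, " predicted probabilit",
            if (hit == 1) "y" else "ies", " at the numeric floor/ceiling (eps = ",
            eps, ")", call. = FALSE)
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Stabilized inverse probability-of-treatment weight
#'
#' The per-person stabilized weight is the product over that person's
#' observed exposure waves of the numerator over denominator probability of
#' the exposure value actually received. Waves after (or during) censoring
#' contribute no factor.
#'
#' @param p_num,p_den Probabilities of the observed exposure value from the
#'   numerator and denominator models. Vectors (one wave) or matrices
#'   (persons x waves, `NA` for unobserved waves).
#' @param observed Optional logical of the same shape; `FALSE` entries are
#'   skipped.
#' @return Per-person weight vector.
#' @examples
#' # one wave: exposed person with p_num = .6, p_den = .3
#' stabilized_iptw(0.6, 0.3)                     # 2
#' stabilized_iptw(c(0.6, 0.5), c(0.3, 1.0))     # product over waves
#' @export
stabilized_iptw <- function(p_num, p_den, observed = NULL) {
  stopifnot(length(p_num) == length(p_den))
  ratio <- p_num / p_den
  if (!is.null(observed)) ratio[!observed] <- NA
  if (is.matrix(ratio)) {
    apply(ratio, 1, function(r) prod(r, na.rm = TRUE))
  } else {
    prod(ratio, na.rm = TRUE)
  }
}

#' Fit per-wave attrition (observation) models and stabilized IPAW
#'
#' Interior-wave attrition is intermittent in this design (the final wave
#' is fully ascertained), so observation is modeled per wave rather than as
#' monotone censoring: for each interior exposure wave, logistic models for
#' "observed at this wave" given the baseline covariates (numerator) and
#' additionally the last observed exposure indicator and time-varying
#' covariate values (denominator). The stabilized attrition weight is the
#' product of numerator over denominator retention probabilities across the
#' waves at which the person was actually observed. Waves with full
#' retention contribute a factor of one without model fitting.
#'
#' @inheritParams fit_exposure_models
#' @return A list of class `attrition_models`: `probs` (tibble of
#'   `person_id`, `t_index`, `c_num`, `c_den` -- retention probabilities),
#'   `ipaw` (per-person tibble), `fits`.
#' @export
fit_attrition_models <- function(cohort, exposure,
                                 baseline_vars = character(),
                                 tv_vars = character(),
                                 eps = 1e-6) {
  base <- baseline_frame(cohort, baseline_vars, tv_vars)
  fr <- attrition_frame(cohort, exposure, tv_vars)
  fr <- dplyr::left_join(fr, base, by = "person_id")
  base_terms <- setdiff(names(base), "person_id")
  ex_obs <- exposure_frame(cohort, exposure)
  t_all <- sort(unique(ex_obs$t_index[!is.na(ex_obs$a)]))
  t_interior <- setdiff(t_all, max(t_all))
  fits <- list()
  probs <- list()
  for (t in t_interior) {
    d <- fr[fr$t_index == t, , drop = FALSE]
    d$c_obs <- as.integer(d$observed)
    if (all(d$c_obs == 1L)) {
      probs[[length(probs) + 1L]] <- tibble::tibble(
        person_id = d$person_id, t_index = t, c_obs = 1L,
        c_num = 1, c_den = 1)
      next
    }
    last_terms <- if (t == 1) character() else
      c("a_last", paste0(tv_vars, "_last"))
    num_terms <- base_terms
    den_terms <- c(base_terms, last_terms)
    cc <- complete.cases(d[unique(c("c_obs", den_terms))])
    d <- drop_unused_factor_levels(d[cc, , drop = FALSE])
    f_num <- reformulate(if (length(num_terms)) num_terms else "1",
                         response = "c_obs")
    f_den <- reformulate(if (length(den_terms)) den_terms else "1",
                         response = "c_obs")
    m_num <- glm(f_num, data = d, family = binomial())
    m_den <- glm(f_den, data = d, family = binomial())
    check_separation(m_den, t)
    probs[[length(probs) + 1L]] <- tibble::tibble(
      person_id = d$person_id, t_index = t, c_obs = d$c_obs,
      c_num = clamp_prob(predict(m_num, type = "response"), eps),
      c_den = clamp_prob(predict(m_den, type = "response"), eps))
    fits[[as.character(t)]] <- list(numerator = m_num, denominator = m_den)
  }
  probs <- dplyr::bind_rows(probs)
  ids <- unique(fr$person_id)
  if (nrow(probs)) {
    obs_probs <- probs[probs$c_obs == 1L, , drop = FALSE]
    w <- tapply(obs_probs$c_num / obs_probs$c_den, obs_probs$person_id, prod)
    ipaw <- tibble::tibble(person_id = ids,
                           ipaw = as.numeric(w[ids]))
    ipaw$ipaw[is.na(ipaw$ipaw)] <- 1
  } else {
    ipaw <- tibble::tibble(person_id = ids, ipaw = 1)
  }
  structure(list(probs = probs, ipaw = ipaw, fits = fits, eps = eps),
            class = "attrition_models")
}

#' Combine treatment and attrition weights, with optional truncation
#'
#' The analysis weight is the product of the stabilized treatment and
#' attrition weights. Truncation, when requested, clamps the combined
#' weight to the stated sample percentiles; the untruncated column is
#' always retained. Truncation is off by default.
#'
#' @param iptw,ipaw Per-person weight tibbles (`person_id` + weight column)
#'   or bare numeric vectors of equal length.
#' @param truncation `NULL`, or a length-2 percentile pair such as
#'   `c(1, 99)` with the lower value in (0, 50) and the upper in (50, 100).
#' @return A tibble of class `weight_table`: `person_id`, `iptw`, `ipaw`,
#'   `combined`, `truncated`.
#' @examples
#' combine_and_truncate(tibble::tibble(person_id = "p1", iptw = 2),
#'                      tibble::tibble(person_id = "p1", ipaw = 1.5))
#' @export
combine_and_truncate <- function(iptw, ipaw, truncation = NULL) {
  if (is.numeric(iptw)) iptw <- tibble::tibble(person_id = seq_along(iptw), iptw = iptw)
  if (is.numeric(ipaw)) ipaw <- tibble::tibble(person_id = seq_along(ipaw), ipaw = ipaw)
  tab <- dplyr::inner_join(iptw, ipaw, by = "person_id")
  if (nrow(tab) != nrow(iptw) || nrow(tab) != nrow(ipaw)) {
    stop("iptw and ipaw tables cover different persons", call. = FALSE)
  }
  if (any(tab$iptw <= 0) || any(tab$ipaw <= 0)) {
    stop("all weights must be strictly positive", call. = FALSE)
  }
  tab$combined <- tab$iptw * tab$ipaw
  if (!is.null(truncation)) {
    if (length(truncation) != 2 || truncation[1] <= 0 || truncation[1] >= 50 ||
        truncation[2] <= 50 || truncation[2] >= 100) {
      stop("truncation must be c(lower, upper) with lower in (0,50) and upper in (50,100)",
           call. = FALSE)
    }
    q <- quantile(tab$combined, truncation / 100, type = 7)
    tab$truncated <- pmin(pmax(tab$combined, q[1]), q[2])
  } else {
    tab$truncated <- tab$combined
  }
  class(tab) <- c("weight_table", class(tab))
  tab
}

#' Summarize a weight distribution
#'
#' Mean, SD, range and selected percentiles of the stabilized weights. A
#' correctly specified stabilized weight has mean near one; the summary
#' flags a deviation beyond `tolerance`.
#'
#' @param weights A `weight_table` (from [combine_and_truncate] or
#'   [compute_weights]) or numeric vector.
#' @param column Which column to summarize.
#' @param tolerance Flag threshold for `|mean - 1|`.
#' @return A one-row tibble with the summary statistics and a `flagged`
#'   logical.
#' @export
weight_diagnostics <- function(weights, column = "combined",
                               tolerance = 0.05) {
  w <- if (is.numeric(weights)) weights else weights[[column]]
  qs <- quantile(w, c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99))
  out <- tibble::tibble(mean = mean(w), sd = sd(w), min = min(w),
                        max = max(w),
                        p01 = qs[[1]], p05 = qs[[2]], p25 = qs[[3]],
                        p50 = qs[[4]], p75 = qs[[5]], p95 = qs[[6]],
                        p99 = qs[[7]],
                        flagged = abs(mean(w) - 1) > tolerance)
  if (out$flagged) {
    warning("stabilized-weight mean ", signif(out$mean, 4),
            " deviates from 1 by more than ", tolerance, call. = FALSE)
  }
  out
}

#' Build the full stabilized weight table for a cohort
#'
#' Orchestrates [fit_exposure_models], [fit_attrition_models],
#' [stabilized_iptw] and [combine_and_truncate]: the Model-2 weights use
#' history, baseline and current time-varying covariates in the exposure
#' denominators; the Model-3 ("adjusted") weights additionally condition on
#' the other practices' current indicators via `other_exposures`.
#'
#' @inheritParams fit_exposure_models
#' @param model 2 (stabilized) or 3 (adjusted stabilized; requires
#'   `other_exposures`).
#' @param use_ipaw Multiply in the stabilized attrition weights
#'   (default `TRUE`).
#' @param truncation Optional percentile pair, see [combine_and_truncate].
#' @return A `weight_table` tibble with attributes `exposure_models`,
#'   `attrition_models` and `probs` (the per-wave probability audit table).
#' @export
compute_weights <- function(cohort, exposure, model = 2,
                            baseline_vars = character(),
                            tv_vars = character(),
                            other_exposures = NULL,
                            use_ipaw = TRUE,
                            eps = 1e-6, truncation = NULL) {
  stopifnot(model %in% c(2, 3))
  if (model == 3 && is.null(other_exposures)) {
    stop("model 3 requires `other_exposures` (the other practices' series)",
         call. = FALSE)
  }
  if (model == 2) other_exposures <- NULL
  em <- fit_exposure_models(cohort, exposure, baseline_vars, tv_vars,
                            other_exposures, eps)
  iptw_w <- tapply(em$probs$p_num / em$probs$p_den, em$probs$person_id, prod)
  ids <- unique(exposure$person_id)
  iptw <- tibble::tibble(person_id = ids,
                         iptw = as.numeric(iptw_w[ids]))
  iptw$iptw[is.na(iptw$iptw)] <- 1
  if (use_ipaw) {
    am <- fit_attrition_models(cohort, exposure, baseline_vars, tv_vars, eps)
    ipaw <- am$ipaw
  } else {
    am <- NULL
    ipaw <- tibble::tibble(person_id = ids, ipaw = 1)
  }
  tab <- combine_and_truncate(iptw, ipaw, truncation)
  probs <- em$probs
  if (!is.null(am) && nrow(am$probs)) {
    probs <- dplyr::full_join(probs,
                              am$probs[c("person_id", "t_index", "c_num", "c_den")],
                              by = c("person_id", "t_index"))
  }
  attr(tab, "exposure_models") <- em
  attr(tab, "attrition_models") <- am
  attr(tab, "probs") <- probs
  attr(tab, "model") <- model
  tab
}

#' Pseudo-population balance diagnostic
#'
#' In the pseudo-population created by the stabilized treatment weights the
#' current exposure depends only on the stabilization (numerator)
#' covariates -- exposure history and baseline -- and the current
#' time-varying confounder carries no further information. This fits, per
#' exposure wave, a weighted logistic regression of the exposure indicator
#' on the confounder plus the numerator covariates, weighting each record
#' by the cumulative stabilized weight through that wave, and reports the
#' confounder coefficient with a robust (sandwich) z statistic. For
#' correctly specified weights |z| < 3 at every wave is the expected
#' behavior; with the weights removed the same coefficient is the (large)
#' confounding signal.
#'
#' @param cohort,exposure,baseline_vars,tv_vars As in
#'   [fit_exposure_models].
#' @param weights A `weight_table` from [compute_weights] (its per-wave
#'   probability audit table supplies the cumulative weights).
#' @param tv_var Confounder column to test (defaults to the first of
#'   `tv_vars`).
#' @return A tibble with one row per wave: coefficient, robust SE, z.
#' @export
balance_diagnostics <- function(cohort, exposure, weights,
                                baseline_vars = character(),
                                tv_vars = character(),
                                tv_var = tv_vars[1]) {
  probs <- attr(weights, "probs")
  if (is.null(probs)) {
    stop("weight table lacks the per-wave probability audit table",
         call. = FALSE)
  }
  probs <- dplyr::arrange(probs[!is.na(probs$p_num), ], person_id, t_index)
  probs <- dplyr::mutate(dplyr::group_by(probs, person_id),
                         cumw = cumprod(p_num / p_den))
  probs <- dplyr::ungroup(probs)
  base <- baseline_frame(cohort, baseline_vars, tv_vars)
  base_terms <- setdiff(names(base), "person_id")
  fr <- exposure_frame(cohort, exposure, unique(c(tv_vars, tv_var)))
  fr <- dplyr::left_join(fr, base, by = "person_id")
  fr <- dplyr::inner_join(fr, probs[c("person_id", "t_index", "cumw")],
                          by = c("person_id", "t_index"))
  out <- list()
  for (t in sort(unique(fr$t_index[!is.na(fr$a)]))) {
    d <- fr[fr$t_index == t & !is.na(fr$a) & !is.na(fr[[tv_var]]), ]
    hist_terms <- if (t == 1) character() else if (t == 2) "a_lag" else
      c("a_lag", "cum_lag")
    d <- drop_unused_factor_levels(d)
    fit <- suppressWarnings(
      glm(reformulate(c(tv_var, hist_terms, base_terms), "a"), data = d,
          family = quasibinomial(), weights = d$cumw))
    vc <- sandwich::vcovHC(fit, type = "HC0")
    co <- coef(fit)[[tv_var]]
    se <- sqrt(vc[tv_var, tv_var])
    out[[length(out) + 1L]] <- tibble::tibble(t_index = t, coef = co,
                                              se = se, z = co / se)
  }
  dplyr::bind_rows(out)
}
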