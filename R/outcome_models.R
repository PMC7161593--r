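# Person-level outcome frame: wave-9 outcome, cumulative exposure,
# baseline covariates (+ wave-1 time-varying values), optional other
# cumulative exposures.
outcome_frame <- function(cohort, exposure, outcome,
                          baseline_vars = character(),
                          w1_tv_vars = character(),
                          other_exposures = NULL) {
  oc_col <- switch(outcome, cigarette = "outcome_cig", alcohol = "outcome_alc",
                   stop("outcome must be 'cigarette' or 'alcohol'", call. = FALSE))
  w9 <- cohort[cohort$wave == 9L, c("person_id", oc_col)]
  names(w9)[2] <- "y"
  cum <- unique(exposure[c("person_id", "cumulative")])
  d <- dplyr::inner_join(w9, cum, by = "person_id")
  d <- dplyr::left_join(d, baseline_frame(cohort, baseline_vars, w1_tv_vars),
                        by = "person_id")
  if (!is.null(other_exposures)) {
    for (nm in names(other_exposures)) {
      oc <- unique(other_exposures[[nm]][c("person_id", "cumulative")])
      names(oc)[2] <- paste0("cum_", nm)
      d <- dplyr::left_join(d, oc, by = "person_id")
    }
  }
  d
}

# Robust sandwich effect summary for the cumulative-exposure term. HC3
# (leverage-corrected) rather than HC0: a handful of very large stabilized
# weights create high-leverage rows whose uncorrected sandwich understates
# the sampling variance.
effect_row <- function(fit, model, outcome, practice, cutoff, term = "cumulative") {
  co <- coef(fit)
  aliased <- names(co)[is.na(co)]
  if (length(aliased)) {
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  vc <- sandwich::vcovHC(fit, type = "HC3")
  beta <- co[[term]]
  se <- sqrt(vc[term, term])
  tibble::tibble(model = model, outcome = outcome, practice = practice,
                 cutoff = cutoff, beta = beta, se = se,
                 ci95_low = beta - 1.96 * se, ci95_high = beta + 1.96 * se,
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 n_used = length(fit$residuals))
}

#' Conventional covariate-adjusted regression (Model 1)
#'
#' Unweighted least squares of the wave-9 outcome frequency on the
#' cumulative exposure count, controlling for the baseline time-invariant
#' covariates, the wave-1 values of the time-varying covariates and
#' (optionally) the other two practices' cumulative counts. Reported with
#' heteroskedasticity-robust (HC0) standard errors. Under
#' exposure-confounder feedback this estimator is biased -- it is the
#' comparison arm for the weighted analysis, not the recommendation.
#'
#' @param cohort A cohort tibble.
#' @param exposure Derived exposure tibble ([derive_exposures]).
#' @param outcome `"cigarette"` or `"alcohol"`.
#' @param baseline_vars Time-invariant covariate columns.
#' @param tv_vars Time-varying covariate columns (their wave-1 values are
#'   the controls).
#' @param other_exposures Named list of the other practices' exposure
#'   tibbles (their cumulative counts enter as controls), or `NULL`.
#' @return A one-row effect tibble: `model`, `outcome`, `practice`,
#'   `cutoff`, `beta` (change in outcome frequency per additional exposure
#'   wave), robust `se`, `ci95_low`, `ci95_high`, `p_value`, `n_used`. The
#'   fitted `lm` is attached as attribute `fit`.
#' @export
fit_conventional <- function(cohort, exposure,
                             outcome = c("cigarette", "alcohol"),
                             baseline_vars = character(),
                             tv_vars = character(),
                             other_exposures = NULL) {
  outcome <- match.arg(outcome)
  d <- outcome_frame(cohort, exposure, outcome, baseline_vars, tv_vars,
                     other_exposures)
  d <- drop_unused_factor_levels(d[complete.cases(d), , drop = FALSE])
  terms <- setdiff(names(d), c("person_id", "y"))
  fit <- lm(reformulate(terms, "y"), data = d)
  out <- effect_row(fit, model = 1L, outcome = outcome,
                    practice = exposure$practice[1], cutoff = exposure$cutoff[1])
  attr(out, "fit") <- fit
  out
}

#' Weighted marginal structural model fit (Models 2 and 3)
#'
#' Weighted least squares of the wave-9 outcome on the cumulative exposure
#' count and the baseline covariates only -- time-varying confounding is
#' handled entirely by the weights, so the time-varying covariates are
#' deliberately *not* in the outcome model. Weights are treated as
#' probability weights: point estimates from `lm(..., weights = w)` with a
#' sandwich (HC0) variance.
#'
#' @inheritParams fit_conventional
#' @param weights A `weight_table` from [compute_weights].
#' @param use Weight column: `"combined"` (default), `"truncated"` or
#'   `"iptw"` (no attrition weighting).
#' @return A one-row effect tibble as in [fit_conventional], with `model`
#'   taken from the weight table (2 or 3).
#' @export
fit_msm <- function(cohort, exposure, outcome = c("cigarette", "alcohol"),
                    weights, baseline_vars = character(),
                    tv_vars = character(), use = "combined") {
  outcome <- match.arg(outcome)
  stopifnot(use %in% c("combined", "truncated", "iptw"))
  d <- outcome_frame(cohort, exposure, outcome, baseline_vars, tv_vars)
  uncovered <- setdiff(d$person_id, weights$person_id)
  if (length(uncovered)) {
    stop("weight table does not cover ", length(uncovered),
         " person(s) in the analysis set", call. = FALSE)
  }
  d <- dplyr::inner_join(d, weights[c("person_id", use)], by = "person_id")
  d <- drop_unused_factor_levels(d[complete.cases(d), , drop = FALSE])
  w <- d[[use]]
  if (any(w <= 0)) stop("non-positive analysis weight", call. = FALSE)
  terms <- setdiff(names(d), c("person_id", "y", use))
  d$.w <- w
  fit <- lm(reformulate(terms, "y"), data = d, weights = .w)
  model_tag <- attr(weights, "model") %||% 2L
  out <- effect_row(fit, model = as.integer(model_tag), outcome = outcome,
                    practice = exposure$practice[1], cutoff = exposure$cutoff[1])
  attr(out, "fit") <- fit
  out
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Effect-estimate table over the practice/cutoff/model/outcome grid
#'
#' Reproduces the shape of the study's summary tables: one row per
#' practice, cutoff, model (1 = conventional, 2 = stabilized weights,
#' 3 = adjusted stabilized weights) and outcome, with the slope per
#' additional exposure wave, its robust 95% CI and significance stars
#' (0.05 / 0.01 / 0.001).
#'
#' @param cohort A cohort tibble.
#' @param practices Character vector of practices to run.
#' @param cutoffs Named list of cutoff vectors (defaults to
#'   [practice_cutoffs]).
#' @param models Integer subset of `c(1, 2, 3)`.
#' @param outcomes Character subset of `c("cigarette", "alcohol")`.
#' @param baseline_vars,tv_vars Covariate roles, as in [fit_conventional].
#' @param use_ipaw Multiply attrition weights into the analysis weights.
#' @param eps,truncation Passed to [compute_weights].
#' @return A tidy tibble of effect rows with a `stars` column.
#' @export
run_table <- function(cohort,
                      practices = names(practice_cutoffs()),
                      cutoffs = practice_cutoffs(),
                      models = c(1, 2, 3),
                      outcomes = c("cigarette", "alcohol"),
                      baseline_vars = character(),
                      tv_vars = character(),
                      use_ipaw = TRUE, eps = 1e-6, truncation = NULL) {
  all_series <- list()
  for (p in practices) {
    for (co in cutoffs[[p]]) {
      all_series[[series_key(p, co)]] <- derive_exposures(cohort, p, co)
    }
  }
  # one representative series per other practice (first cutoff)
  rows <- list()
  for (p in practices) {
    others <- setdiff(names(practice_cutoffs()), p)
    other_series <- lapply(others, function(q) {
      key <- series_key(q, cutoffs[[q]][1] %||% practice_cutoffs()[[q]][1])
      all_series[[key]] %||% derive_exposures(cohort, q, practice_cutoffs()[[q]][1])
    })
    names(other_series) <- others
    for (co in cutoffs[[p]]) {
      ex <- all_series[[series_key(p, co)]]
      w2 <- if (any(c(2, 3) %in% models)) {
        compute_weights(cohort, ex, model = 2, baseline_vars = baseline_vars,
                        tv_vars = tv_vars, use_ipaw = use_ipaw, eps = eps,
                        truncation = truncation)
      }
      w3 <- if (3 %in% models) {
        compute_weights(cohort, ex, model = 3, baseline_vars = baseline_vars,
                        tv_vars = tv_vars, other_exposures = other_series,
                        use_ipaw = use_ipaw, eps = eps, truncation = truncation)
      }
      for (oc in outcomes) {
        if (1 %in% models) {
          rows[[length(rows) + 1L]] <- fit_conventional(
            cohort, ex, oc, baseline_vars, tv_vars, other_series)
        }
        if (2 %in% models) {
          rows[[length(rows) + 1L]] <- fit_msm(
            cohort, ex, oc, w2, baseline_vars, tv_vars)
        }
        if (3 %in% models) {
          rows[[length(rows) + 1L]] <- fit_msm(
            cohort, ex, oc, w3, baseline_vars, tv_vars)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$stars <- significance_stars(out$p_value)
  dplyr::arrange(out, practice, dplyr::desc(cutoff), outcome, model)
}

series_key <- function(practice, cutoff) paste0(practice, "@", cutoff)
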