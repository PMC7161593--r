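# Internal builders that reshape a long cohort + derived exposure series
# into per-wave modeling frames for the weight and outcome models.

# Baseline frame: one row per person with the time-invariant covariates and
# the wave-1 values of the requested time-varying covariates (suffix "_w1").
baseline_frame <- function(cohort, baseline_vars = character(),
                           w1_tv_vars = character()) {
  w1 <- cohort[cohort$wave == 1L, , drop = FALSE]
  out <- tibble::tibble(person_id = w1$person_id)
  for (v in baseline_vars) {
    if (!v %in% names(cohort)) stop("no such baseline column: ", v, call. = FALSE)
    out[[v]] <- w1[[v]]
  }
  for (v in w1_tv_vars) {
    if (!v %in% names(cohort)) stop("no such covariate column: ", v, call. = FALSE)
    out[[paste0(v, "_w1")]] <- w1[[v]]
  }
  out
}

# Person-wave frame over the exposure waves with the exposure indicator,
# carry-forward history terms and current time-varying covariates.
# History convention: a_lag is the most recent non-missing indicator before
# t (0 before the first wave); cum_lag is the missing-as-unexposed
# cumulative count through t-1.
exposure_frame <- function(cohort, exposure, tv_vars = character()) {
  ew <- exposure_waves()
  ex <- dplyr::arrange(exposure, person_id, t_index)
  ids <- unique(ex$person_id)
  n <- length(ids)
  amat <- matrix(NA_integer_, n, length(ew),
                 dimnames = list(ids, paste0("t", seq_along(ew))))
  amat[cbind(match(ex$person_id, ids), ex$t_index)] <- ex$indicator
  filled <- amat
  filled[is.na(filled)] <- 0L
  cum <- t(apply(filled, 1, cumsum))
  cum_lag <- cbind(0L, cum[, -ncol(cum), drop = FALSE])
  # last observed indicator before t
  a_lag <- matrix(0L, n, length(ew))
  run <- rep(0L, n)
  for (t in seq_along(ew)) {
    a_lag[, t] <- run
    seen <- !is.na(amat[, t])
    run[seen] <- amat[seen, t]
  }
  fr <- tibble::tibble(
    person_id = rep(ids, times = length(ew)),
    t_index = rep(seq_along(ew), each = n),
    wave = rep(ew, each = n),
    a = as.integer(amat),
    a_lag = as.integer(a_lag),
    cum_lag = as.integer(cum_lag)
  )
  if (length(tv_vars)) {
    tv <- cohort[cohort$wave %in% ew, c("person_id", "wave", tv_vars)]
    fr <- dplyr::left_join(fr, tv, by = c("person_id", "wave"))
  }
  obs <- cohort[cohort$wave %in% ew, c("person_id", "wave", "observed")]
  dplyr::left_join(fr, obs, by = c("person_id", "wave"))
}

# Carry-forward covariate state entering each wave's attrition model:
# the last observed exposure indicator and time-varying covariate values
# before wave t (wave-1 values before the first exposure wave).
attrition_frame <- function(cohort, exposure, tv_vars = character()) {
  ew <- exposure_waves()
  fr <- exposure_frame(cohort, exposure, tv_vars)
  fr <- dplyr::arrange(fr, person_id, t_index)
  ids <- unique(fr$person_id)
  n <- length(ids)
  w1 <- cohort[cohort$wave == 1L, , drop = FALSE]
  w1 <- w1[match(ids, w1$person_id), , drop = FALSE]
  out <- fr[c("person_id", "t_index", "wave", "observed")]
  out$a_last <- 0L
  for (v in tv_vars) out[[paste0(v, "_last")]] <- NA
  run_a <- rep(0L, n)
  run_tv <- lapply(tv_vars, function(v) w1[[v]])
  names(run_tv) <- tv_vars
  for (t in seq_along(ew)) {
    idx <- which(fr$t_index == t)
    idx <- idx[match(ids, fr$person_id[idx])]
    rows <- which(out$t_index == t)
    rows <- rows[match(ids, out$person_id[rows])]
    out$a_last[rows] <- run_a
    for (v in tv_vars) out[[paste0(v, "_last")]][rows] <- run_tv[[v]]
    obs <- fr$observed[idx] & !is.na(fr$a[idx])
    run_a[obs] <- fr$a[idx][obs]
    for (v in tv_vars) {
      cur <- fr[[v]][idx]
      upd <- obs & !is.na(cur)
      run_tv[[v]][upd] <- cur[upd]
    }
  }
  out
}

# Column-bind other practices' current-wave indicators (model 3 adjustment),
# missing treated as unexposed within the fitting rows.
add_other_practices <- function(fr, other_exposures) {
  for (nm in names(other_exposures)) {
    oe <- other_exposures[[nm]]
    key <- paste(oe$person_id, oe$t_index)
    ind <- oe$indicator
    ind[is.na(ind)] <- 0L
    fr[[paste0("other_", nm)]] <- ind[match(paste(fr$person_id, fr$t_index), key)]
  }
  fr
}

drop_unused_factor_levels <- function(df) {
  for (j in seq_along(df)) if (is.factor(df[[j]])) df[[j]] <- droplevels(df[[j]])
  df
}
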