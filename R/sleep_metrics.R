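#' Nightly sleep duration from bed and wake clock times
#'
#' Duration is the clock distance from bed time to wake time, crossing
#' midnight whenever the wake time is at or before the bed time on the
#' 24-hour dial. Equal bed and wake times are rejected as ambiguous
#' (0 vs 24 h).
#'
#' @param bed,wake Clock times in minutes since midnight (see [parse_clock])
#'   or "HH:MM" strings. Vectorized; `NA` propagates.
#' @return Duration in hours, in the open interval (0, 24).
#' @examples
#' sleep_duration("23:30", "06:30")  # 7
#' sleep_duration("01:00", "07:00")  # 6, no midnight crossing
#' @export
sleep_duration <- function(bed, wake) {
  if (is.character(bed)) bed <- parse_clock(bed)
  if (is.character(wake)) wake <- parse_clock(wake)
  both <- !is.na(bed) & !is.na(wake)
  if (any(both & bed == wake)) {
    stop("bed time equals wake time: duration ambiguous (0 vs 24 h)",
         call. = FALSE)
  }
  mins <- (wake - bed) %% 1440
  ifelse(both, mins / 60, NA_real_)
}

#' Weekly average nightly sleep
#'
#' The week is five school nights plus two weekend nights; total weekly
#' sleep divided by seven.
#'
#' @param weekday_h,weekend_h Nightly durations in hours, each in (0, 24).
#' @return `(5 * weekday_h + 2 * weekend_h) / 7` in hours.
#' @examples
#' weekly_average_sleep(7, 9)  # 53/7
#' @export
weekly_average_sleep <- function(weekday_h, weekend_h) {
  ok <- is.na(weekday_h) | (weekday_h > 0 & weekday_h < 24)
  ok2 <- is.na(weekend_h) | (weekend_h > 0 & weekend_h < 24)
  if (!all(ok & ok2)) stop("durations must lie in (0, 24) hours", call. = FALSE)
  (5 * weekday_h + 2 * weekend_h) / 7
}

#' Short-sleep indicator
#'
#' Short sleep is a weekly average strictly below the cutoff. The study
#' cutoffs are 8, 7 and 6 hours; other values require `strict_cutoffs =
#' FALSE`.
#'
#' @param weekly_h Weekly average nightly sleep in hours.
#' @param cutoff Hours; one of 8, 7, 6 unless `strict_cutoffs = FALSE`.
#' @param strict_cutoffs Enforce the canonical cutoff set.
#' @return Integer 0/1 (`NA` propagates).
#' @export
short_sleep_indicator <- function(weekly_h, cutoff, strict_cutoffs = TRUE) {
  if (strict_cutoffs && !cutoff %in% c(8, 7, 6)) {
    stop("short-sleep cutoff must be 8, 7 or 6 h (set strict_cutoffs = FALSE to override)",
         call. = FALSE)
  }
  as.integer(weekly_h < cutoff)
}

#' Social jetlag from weekday and weekend bedtimes
#'
#' Weekend bedtime minus weekday bedtime, in hours; positive when bedtime is
#' later at the weekend. Bedtimes on the clock interval \[12:00, 24:00) are
#' taken as the same evening, and times in \[00:00, 12:00) as after midnight
#' of the following calendar day, so that a weekday bedtime of 23:00 and a
#' weekend bedtime of 01:00 yield +2 h rather than -22 h. Antisymmetric in
#' its arguments.
#'
#' @param weekday_bed,weekend_bed Clock times (minutes since midnight or
#'   "HH:MM").
#' @return Signed hours.
#' @examples
#' social_jetlag("23:00", "01:00")  # +2
#' social_jetlag("00:30", "23:30")  # -1
#' @export
social_jetlag <- function(weekday_bed, weekend_bed) {
  if (is.character(weekday_bed)) weekday_bed <- parse_clock(weekday_bed)
  if (is.character(weekend_bed)) weekend_bed <- parse_clock(weekend_bed)
  # fold post-midnight bedtimes onto the next day
  adj <- function(m) ifelse(m < 720, m + 1440, m)
  (adj(weekend_bed) - adj(weekday_bed)) / 60
}

#' Social-jetlag indicator
#'
#' Jetlag at or above the cutoff (inclusive). Study cutoffs: 2, 1, 0.5 h.
#'
#' @param jetlag_h Signed jetlag in hours.
#' @param cutoff Hours; one of 2, 1, 0.5 unless `strict_cutoffs = FALSE`.
#' @param strict_cutoffs Enforce the canonical cutoff set.
#' @return Integer 0/1 (`NA` propagates).
#' @export
jetlag_indicator <- function(jetlag_h, cutoff, strict_cutoffs = TRUE) {
  if (strict_cutoffs && !cutoff %in% c(2, 1, 0.5)) {
    stop("jetlag cutoff must be 2, 1 or 0.5 h (set strict_cutoffs = FALSE to override)",
         call. = FALSE)
  }
  as.integer(jetlag_h >= cutoff)
}

#' Sleep-disturbance sum score and indicator
#'
#' Three items (difficulty falling asleep, early waking, disturbed night
#' sleep), each rated 0--4; the wave's disturbance score is their sum
#' (0--12) and disturbance is present when the sum exceeds zero.
#'
#' @param item1,item2,item3 Integer ratings 0--4. Vectorized; if any item is
#'   `NA` the score is `NA`.
#' @return `disturbance_score()`: integer 0--12; `disturbance_indicator()`:
#'   integer 0/1.
#' @examples
#' disturbance_score(1, 0, 2)       # 3
#' disturbance_indicator(disturbance_score(0, 0, 0))  # 0
#' @export
disturbance_score <- function(item1, item2, item3) {
  items <- cbind(item1, item2, item3)
  if (any(!is.na(items) & (items < 0 | items > 4))) {
    stop("disturbance items must be in 0-4", call. = FALSE)
  }
  as.integer(item1 + item2 + item3)
}

#' @param score Sum score from [disturbance_score].
#' @rdname disturbance_score
#' @export
disturbance_indicator <- function(score) {
  as.integer(score > 0)
}

#' Cumulative exposure over the five exposure waves
#'
#' Count of waves at which the dichotomized practice was present. A missing
#' wave indicator (unobserved wave or item non-response) contributes zero to
#' the sum -- the person is retained and the wave's attrition is handled by
#' the attrition weights, not by dropping the person. If every wave is
#' missing the cumulative count itself is missing.
#'
#' @param indicators Numeric vector (or matrix, persons x waves) of 0/1
#'   indicators with possible `NA`.
#' @return Integer count(s) in 0--5, `NA` when all waves are missing.
#' @examples
#' cumulative_exposure(c(1, 0, 1, 1, 0))   # 3
#' cumulative_exposure(c(1, NA, 1, 0, 1))  # 3
#' @export
cumulative_exposure <- function(indicators) {
  if (is.matrix(indicators)) {
    n_obs <- rowSums(!is.na(indicators))
    out <- as.integer(rowSums(indicators, na.rm = TRUE))
    out[n_obs == 0] <- NA_integer_
    return(out)
  }
  if (all(is.na(indicators))) return(NA_integer_)
  as.integer(sum(indicators, na.rm = TRUE))
}

#' The three practices and their study cutoffs
#' @return Named list of cutoff vectors per practice.
#' @export
practice_cutoffs <- function() {
  list(short_sleep = c(8, 7, 6),
       social_jetlag = c(2, 1, 0.5),
       disturbance = c(0))
}

#' Derive per-wave exposure indicators and cumulative counts
#'
#' Applies the practice definition to every observed exposure-wave record of
#' the cohort: weekly average sleep below the cutoff (`short_sleep`),
#' weekend-minus-weekday bedtime at or above the cutoff (`social_jetlag`),
#' or disturbance sum score above zero (`disturbance`; the `cutoff` argument
#' is ignored for this practice). Records of unobserved waves, or with the
#' needed raw fields missing, yield `NA` indicators.
#'
#' @param cohort A cohort tibble (see [read_cohort]).
#' @param practice One of `"short_sleep"`, `"social_jetlag"`,
#'   `"disturbance"`.
#' @param cutoff Practice-specific threshold (hours; unused for
#'   `disturbance`).
#' @return A tibble with one row per person and exposure wave:
#'   `person_id`, `wave`, `t_index` (1--5), `indicator`, plus a per-person
#'   `cumulative` column (constant within person).
#' @export
derive_exposures <- function(cohort,
                             practice = c("short_sleep", "social_jetlag",
                                          "disturbance"),
                             cutoff = NULL) {
  practice <- match.arg(practice)
  if (is.null(cutoff)) cutoff <- practice_cutoffs()[[practice]][1]
  ew <- exposure_waves()
  d <- cohort[cohort$wave %in% ew, ]
  ind <- rep(NA_integer_, nrow(d))
  obs <- d$observed
  if (practice == "short_sleep") {
    wd <- sleep_duration(parse_clock(d$weekday_bed), parse_clock(d$weekday_wake))
    we <- sleep_duration(parse_clock(d$weekend_bed), parse_clock(d$weekend_wake))
    avg <- (5 * wd + 2 * we) / 7
    ind <- short_sleep_indicator(avg, cutoff)
  } else if (practice == "social_jetlag") {
    jl <- social_jetlag(parse_clock(d$weekday_bed), parse_clock(d$weekend_bed))
    ind <- jetlag_indicator(jl, cutoff)
  } else {
    sc <- disturbance_score(d$dist_insomnia, d$dist_early_waking,
                            d$dist_night_waking)
    ind <- disturbance_indicator(sc)
  }
  ind[!obs] <- NA_integer_
  out <- tibble::tibble(person_id = d$person_id,
                        wave = d$wave,
                        t_index = match(d$wave, ew),
                        practice = practice,
                        cutoff = cutoff,
                        indicator = ind)
  out <- dplyr::arrange(out, person_id, t_index)
  cum <- tapply(out$indicator, out$person_id, function(x) {
    if (all(is.na(x))) NA_integer_ else as.integer(sum(x, na.rm = TRUE))
  })
  out$cumulative <- as.integer(cum[out$person_id])
  out
}

#' Derive the full practice-by-cutoff battery
#'
#' Runs [derive_exposures] for every practice and cutoff combination
#' (8/7/6 h short sleep, 2/1/0.5 h jetlag, disturbance sum > 0).
#' @param cohort A cohort tibble.
#' @return A tibble stacking the per-combination results.
#' @export
derive_all_exposures <- function(cohort) {
  grid <- practice_cutoffs()
  purrr::map_dfr(names(grid), function(p) {
    purrr::map_dfr(grid[[p]], function(co) derive_exposures(cohort, p, co))
  })
}
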