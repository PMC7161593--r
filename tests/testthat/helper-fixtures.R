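# Small in-code fixtures shared across test files.

# A hand-built six-wave cohort for one or more persons with fully specified
# raw fields; covariates kept minimal.
toy_cohort <- function(ids = "p1") {
  rows <- lapply(ids, function(id) {
    tibble::tibble(
      person_id = id,
      wave = wave_order(),
      observed = TRUE,
      weekday_bed = c(NA, "23:30", "23:00", "00:30", "23:45", "23:00"),
      weekday_wake = c(NA, "06:30", "06:00", "06:30", "06:45", "07:00"),
      weekend_bed = c(NA, "01:00", "23:00", "23:30", "01:45", "23:30"),
      weekend_wake = c(NA, "09:00", "08:00", "08:30", "09:45", "08:30"),
      dist_insomnia = c(NA, 1L, 0L, 0L, 2L, 0L),
      dist_early_waking = c(NA, 0L, 0L, 0L, 1L, 0L),
      dist_night_waking = c(NA, 2L, 0L, 1L, 0L, 0L),
      outcome_cig = c(NA, NA, NA, NA, NA, 2L),
      outcome_alc = c(NA, NA, NA, NA, NA, 1L),
      gender = "female",
      depression = c(0.4, 0.2, 0.1, 0.5, 0.3, 0.2),
      self_substance = c("no", "no", "no", "yes", "yes", NA)
    )
  })
  as_cohort(dplyr::bind_rows(rows),
            time_invariant = "gender",
            time_varying = c("depression", "self_substance"))
}

# Random raw person-wave records for property-style tests of the metric
# battery: minutes-resolution clock times and 0-4 items.
random_sleep_records <- function(n, seed = 1) {
  set.seed(seed)
  bed_wd <- sample(0:1439, n, replace = TRUE)
  bed_we <- sample(0:1439, n, replace = TRUE)
  dur_wd <- sample(1:1439, n, replace = TRUE)  # avoid bed == wake
  dur_we <- sample(1:1439, n, replace = TRUE)
  tibble::tibble(
    weekday_bed = bed_wd,
    weekday_wake = (bed_wd + dur_wd) %% 1440L,
    weekend_bed = bed_we,
    weekend_wake = (bed_we + dur_we) %% 1440L,
    i1 = sample(0:4, n, replace = TRUE),
    i2 = sample(0:4, n, replace = TRUE),
    i3 = sample(0:4, n, replace = TRUE)
  )
}

# Analysis covariate roles matched to the synthetic generator.
sim_baseline <- "gender"
sim_tv <- "depression"
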