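test_that("sleep duration handles midnight crossing and rejects bed == wake", {
  expect_equal(sleep_duration("23:30", "06:30"), 7)
  expect_equal(sleep_duration("01:00", "07:00"), 6)
  expect_equal(sleep_duration("22:00", "10:00"), 12)
  expect_error(sleep_duration("22:00", "22:00"), "ambiguous")
  d <- sleep_duration(parse_clock(c("23:00", NA)), parse_clock(c("07:00", "06:00")))
  expect_equal(d, c(8, NA))
})

test_that("weekly average uses the five-plus-two night split", {
  expect_equal(weekly_average_sleep(7, 9), 53 / 7)
  expect_equal(weekly_average_sleep(8, 8), 8)
  expect_equal(weekly_average_sleep(6, 10), 50 / 7)
  expect_error(weekly_average_sleep(0, 8), "in \\(0, 24\\)")
})

test_that("short-sleep cutoff is strict and jetlag cutoff inclusive", {
  expect_equal(short_sleep_indicator(7.571, 8), 1L)
  expect_equal(short_sleep_indicator(8, 8), 0L)   # "less than" is strict
  expect_equal(short_sleep_indicator(5.9, 6), 1L)
  expect_error(short_sleep_indicator(7, 5), "cutoff")
  expect_equal(short_sleep_indicator(4, 5, strict_cutoffs = FALSE), 1L)

  expect_equal(jetlag_indicator(2, 2), 1L)        # "at or above" is inclusive
  expect_equal(jetlag_indicator(0.49, 0.5), 0L)
  expect_equal(jetlag_indicator(-1, 0.5), 0L)
  expect_error(jetlag_indicator(1, 3), "cutoff")
})

test_that("social jetlag follows the bedtime-day convention and is antisymmetric", {
  expect_equal(social_jetlag("23:00", "01:00"), 2)
  expect_equal(social_jetlag("23:00", "23:00"), 0)
  expect_equal(social_jetlag("00:30", "23:30"), -1)
  r <- random_sleep_records(500, seed = 42)
  expect_equal(social_jetlag(r$weekday_bed, r$weekend_bed),
               -social_jetlag(r$weekend_bed, r$weekday_bed))
})

test_that("disturbance score sums items and flags any positive score", {
  expect_equal(disturbance_score(0, 0, 0), 0L)
  expect_equal(disturbance_score(1, 0, 2), 3L)
  expect_equal(disturbance_score(4, 4, 4), 12L)
  expect_error(disturbance_score(5, 0, 0), "0-4")
  expect_equal(disturbance_indicator(c(0L, 3L, 12L)), c(0L, 1L, 1L))
})

test_that("cumulative exposure counts missing waves as unexposed", {
  expect_equal(cumulative_exposure(c(1, 0, 1, 1, 0)), 3L)
  expect_equal(cumulative_exposure(c(0, 0, 0, 0, 0)), 0L)
  expect_equal(cumulative_exposure(c(1, NA, 1, 0, 1)), 3L)
  expect_true(is.na(cumulative_exposure(c(NA, NA, NA, NA, NA))))
  m <- rbind(c(1, 1, 1, 1, 1), c(0, NA, NA, NA, NA), rep(NA, 5))
  expect_equal(cumulative_exposure(m), c(5L, 0L, NA))
})

test_that("indicators nest across cutoffs on random records", {
  r <- random_sleep_records(10000, seed = 7)
  avg <- weekly_average_sleep(
    pmin(pmax(sleep_duration(r$weekday_bed, r$weekday_wake), 0.1), 23.9),
    pmin(pmax(sleep_duration(r$weekend_bed, r$weekend_wake), 0.1), 23.9))
  s6 <- short_sleep_indicator(avg, 6)
  s7 <- short_sleep_indicator(avg, 7)
  s8 <- short_sleep_indicator(avg, 8)
  expect_true(all(s6 <= s7))
  expect_true(all(s7 <= s8))
  jl <- social_jetlag(r$weekday_bed, r$weekend_bed)
  j2 <- jetlag_indicator(jl, 2)
  j1 <- jetlag_indicator(jl, 1)
  j05 <- jetlag_indicator(jl, 0.5)
  expect_true(all(j2 <= j1))
  expect_true(all(j1 <= j05))
  # hence prevalence is monotone in the cutoff, as in the study's battery
  expect_true(mean(s6) <= mean(s7) && mean(s7) <= mean(s8))
  expect_true(mean(j2) <= mean(j1) && mean(j1) <= mean(j05))
})

test_that("derived indicators reproduce the latent exposures for every practice", {
  for (p in names(practice_cutoffs())) {
    co <- practice_cutoffs()[[p]][1]
    cfg <- dgp_preset("confounded", n = 300, seed = 11, practice = p, cutoff = co)
    sim <- simulate_cohort(cfg)
    ex <- derive_exposures(sim$cohort, p, co)
    tr <- sim$truth[!is.na(sim$truth$A), ]
    j <- dplyr::inner_join(ex, tr, by = c("person_id", "t_index"))
    expect_equal(j$indicator, j$A, info = p)
  }
})

test_that("derived cumulative counts match direct summation and full battery runs", {
  cfg <- dgp_preset("confounded", n = 150, seed = 5)
  sim <- simulate_cohort(cfg)
  ex <- derive_exposures(sim$cohort, "short_sleep", 8)
  direct <- tapply(ex$indicator, ex$person_id,
                   function(x) sum(x, na.rm = TRUE))
  expect_equal(unname(ex$cumulative[match(names(direct), ex$person_id)]),
               as.integer(direct))
  battery <- derive_all_exposures(sim$cohort)
  expect_equal(nrow(battery), 7 * 5 * 150)  # 7 practice-cutoff combos
  expect_setequal(unique(battery$practice), names(practice_cutoffs()))
})
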