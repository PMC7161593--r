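test_that("clock parsing round-trips and rejects malformed times", {
  expect_equal(parse_clock("00:00"), 0L)
  expect_equal(parse_clock("23:59"), 1439L)
  expect_equal(format_clock(parse_clock(c("06:05", NA, "23:30"))),
               c("06:05", NA, "23:30"))
  x <- 0:1439
  expect_equal(parse_clock(format_clock(x)), x)
  expect_error(parse_clock("24:00"), "out of range")
  expect_error(parse_clock("7h30"), "malformed")
  expect_error(format_clock(1440), "\\[0, 1439\\]")
})

test_that("cohort CSV round-trips field-identically", {
  cfg <- dgp_preset("survey", n = 40, seed = 3)
  co <- simulate_cohort(cfg)$cohort
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(co))
  for (col in cohort_core_columns()) {
    expect_equal(back[[col]], co[[col]], info = col)
  }
  # numeric covariates survive with full precision
  expect_equal(back$depression, co$depression)
})

test_that("schema renames map raw headers onto canonical fields", {
  co <- simulate_cohort(dgp_preset("confounded", n = 10, seed = 1))$cohort
  renamed <- dplyr::rename(co, id = person_id, wk_bed = weekday_bed)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(renamed, path, na = "")
  sch <- cohort_schema(rename = c(person_id = "id", weekday_bed = "wk_bed"))
  back <- read_cohort(path, sch)
  expect_equal(back$person_id, co$person_id)
  expect_equal(back$weekday_bed, co$weekday_bed)
  expect_error(read_cohort(path, cohort_schema()), "person_id")
})

test_that("validation rejects duplicates, bad waves and out-of-range items", {
  co <- toy_cohort(c("p1", "p2"))
  expect_silent(validate_cohort(co))
  dup <- dplyr::bind_rows(co, co[co$wave == 2 & co$person_id == "p1", ])
  expect_error(validate_cohort(dup), "duplicate.*p1, 2")
  bad_wave <- co
  bad_wave$wave[bad_wave$wave == 6] <- 5L
  expect_error(validate_cohort(bad_wave), "unknown wave")
  bad_item <- co
  bad_item$dist_insomnia[bad_item$wave == 2] <- 5L
  expect_error(validate_cohort(bad_item), "out of range")
  no_w1 <- co[co$wave != 1 | co$person_id != "p2", ]
  expect_error(validate_cohort(no_w1), "wave-1")
  leak <- co
  leak$observed[leak$wave == 3] <- FALSE
  expect_error(validate_cohort(leak), "unobserved rows")
  off_wave <- co
  off_wave$outcome_cig[off_wave$wave == 2] <- 1L
  expect_error(validate_cohort(off_wave), "outside wave 9")
})

test_that("baseline exclusions drop wave-1 users and missing outcomes, idempotently", {
  cfg <- dgp_preset("confounded", n = 100, seed = 21,
                    baseline_use_rate = 0.1, outcome_miss_rate = 0.05)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  w1 <- co[co$wave == 1, ]
  w9 <- co[co$wave == 9, ]
  users <- w1$person_id[w1$self_substance == "yes"]
  noout <- w9$person_id[is.na(w9$outcome_cig) | is.na(w9$outcome_alc)]
  expected_kept <- 100 - length(union(users, noout))
  out <- apply_baseline_exclusions(co, quiet = TRUE)
  expect_equal(length(unique(out$person_id)), expected_kept)
  counts <- attr(out, "exclusion_counts")
  expect_equal(unname(counts["baseline_use"]), length(users))
  expect_equal(unname(counts["missing_outcome"]), length(setdiff(noout, users)))
  again <- apply_baseline_exclusions(out, quiet = TRUE)
  expect_equal(again$person_id, out$person_id)
  expect_message(apply_baseline_exclusions(co), "excluded")
})

test_that("missing-indicator coding adds a level without touching rows or values", {
  co <- toy_cohort("p1")
  co$depression_band <- c("0", "<=1", NA, "<=2", ">2", NA)
  enc <- encode_missing_indicator(co, "depression_band")
  expect_equal(nrow(enc), nrow(co))
  expect_s3_class(enc$depression_band, "factor")
  expect_true("MISSING" %in% levels(enc$depression_band))
  expect_equal(sum(enc$depression_band == "MISSING"), 2)
  expect_equal(as.character(enc$depression_band[1]), "0")
  # zero-missing variable: levels gain MISSING but no value changes
  enc2 <- encode_missing_indicator(co, "gender")
  expect_equal(sum(enc2$gender == "MISSING"), 0)
  expect_true("MISSING" %in% levels(enc2$gender))
  # continuous variable without a declared coding is refused
  expect_error(encode_missing_indicator(co, "depression"), "continuous")
  enc3 <- encode_missing_indicator(co, "dist_insomnia",
                                   declare_categorical = "dist_insomnia")
  expect_equal(sum(enc3$dist_insomnia == "MISSING"), 1)
})

test_that("post-encoding missing counts equal the generator's injection log", {
  cfg <- dgp_preset("survey", n = 500, seed = 9)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  log <- attr(co, "miss_log")
  enc <- encode_missing_indicator(co, "dist_insomnia",
                                  declare_categorical = "dist_insomnia")
  obs_rows <- enc$observed & enc$wave %in% exposure_waves()
  expect_equal(sum(enc$dist_insomnia[obs_rows] == "MISSING"),
               unname(log["items"]))
})
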