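#' Parse and format clock times
#'
#' Survey bed and wake times are recorded as "HH:MM" clock strings.
#' Internally they are held as integer minutes since midnight (0--1439),
#' which keeps the sleep-duration and jetlag arithmetic exact.
#'
#' @param x Character vector of "HH:MM" times (24-hour clock). `NA` allowed.
#' @return `parse_clock()`: integer minutes since midnight; `format_clock()`:
#'   character "HH:MM".
#' @examples
#' parse_clock("23:30")
#' format_clock(parse_clock("06:05"))
#' @export
parse_clock <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    m <- regmatches(x[ok], regexec("^([0-9]{1,2}):([0-9]{2})$", x[ok]))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad)) {
      stop("malformed clock time(s): ", paste(unique(x[ok][bad]), collapse = ", "),
           call. = FALSE)
    }
    hh <- as.integer(vapply(m, `[`, "", 2L))
    mm <- as.integer(vapply(m, `[`, "", 3L))
    if (any(hh > 23L | mm > 59L)) {
      stop("clock time out of range (hours 0-23, minutes 0-59): ",
           paste(unique(x[ok][hh > 23L | mm > 59L]), collapse = ", "),
           call. = FALSE)
    }
    out[ok] <- hh * 60L + mm
  }
  out
}

#' @param minutes Integer vector of minutes since midnight (0--1439).
#' @rdname parse_clock
#' @export
format_clock <- function(minutes) {
  stopifnot(is.numeric(minutes))
  bad <- !is.na(minutes) & (minutes < 0 | minutes > 1439 | minutes != floor(minutes))
  if (any(bad)) stop("minutes must be integers in [0, 1439]", call. = FALSE)
  ifelse(is.na(minutes), NA_character_,
         sprintf("%02d:%02d", minutes %/% 60, minutes %% 60))
}

#' Study wave labels
#'
#' The cohort follows the six survey waves of the source panel; exposures are
#' measured at waves 2, 3, 6, 8 and 9, baseline covariates at wave 1, and the
#' substance-use outcomes at wave 9 only.
#' @return Integer vector of wave labels in follow-up order.
#' @export
wave_order <- function() c(1L, 2L, 3L, 6L, 8L, 9L)

#' Exposure waves (all waves after baseline)
#' @return Integer vector of the five exposure-wave labels.
#' @export
exposure_waves <- function() c(2L, 3L, 6L, 8L, 9L)

# Canonical column names that every cohort must carry.
cohort_core_columns <- function() {
  c("person_id", "wave", "observed",
    "weekday_bed", "weekday_wake", "weekend_bed", "weekend_wake",
    "dist_insomnia", "dist_early_waking", "dist_night_waking",
    "outcome_cig", "outcome_alc")
}

#' Describe a cohort CSV schema
#'
#' A schema maps raw CSV column names onto the canonical cohort fields and
#' declares which additional columns are time-invariant (baseline) and
#' time-varying covariates. The canonical field names are those of
#' [cohort_core_columns]: `person_id`, `wave`, `observed`, the four bed/wake
#' clock columns, the three disturbance items and the two wave-9 outcomes.
#'
#' @param rename Named character vector mapping canonical field name ->
#'   raw CSV column name, for files whose headers differ from the canonical
#'   names. Unlisted fields are assumed to use canonical names.
#' @param time_invariant Character vector of baseline covariate column names.
#' @param time_varying Character vector of time-varying covariate column names.
#' @return A list with class `cohort_schema`.
#' @export
cohort_schema <- function(rename = character(),
                          time_invariant = c("gender", "urbanization",
                                             "township", "puberty",
                                             "expect_college",
                                             "father_ethnicity"),
                          time_varying = c("depression", "self_rated_health",
                                           "academic_rank", "cram_school",
                                           "self_substance", "peer_substance",
                                           "live_parents", "job")) {
  structure(list(rename = rename,
                 time_invariant = time_invariant,
                 time_varying = time_varying),
            class = "cohort_schema")
}

#' Read a cohort schema from a YAML file
#'
#' The YAML file may contain `rename` (a map), `time_invariant` and
#' `time_varying` (lists of column names).
#' @param path Path to a YAML file.
#' @return A `cohort_schema`.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_schema(rename = unlist(y$rename %||% character()),
                time_invariant = unlist(y$time_invariant %||% character()),
                time_varying = unlist(y$time_varying %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a long-format cohort CSV
#'
#' One row per person-wave. Clock times are "HH:MM" strings, disturbance
#' items integers 0--4, outcomes integers 0--7 (wave 9 only). Missing values
#' are empty cells or literal "NA". The file is validated on read: duplicate
#' (person, wave) pairs, unknown wave labels and out-of-range item values are
#' hard errors.
#'
#' @param path CSV file path.
#' @param schema A [cohort_schema] (or path to a YAML schema file).
#' @return A validated cohort tibble with attributes `time_invariant`,
#'   `time_varying` and `wave_order`.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "cohort_schema"))
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                         col_types = readr::cols(.default = readr::col_character()))
  # undo header renames: canonical <- raw
  if (length(schema$rename)) {
    for (canon in names(schema$rename)) {
      rawname <- schema$rename[[canon]]
      if (!rawname %in% names(raw)) {
        stop("schema maps '", canon, "' to missing column '", rawname, "'",
             call. = FALSE)
      }
      names(raw)[names(raw) == rawname] <- canon
    }
  }
  missing_cols <- setdiff(cohort_core_columns(), names(raw))
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  co <- tibble::as_tibble(raw)
  co$wave <- suppressWarnings(as.integer(co$wave))
  co$observed <- tolower(co$observed) %in% c("true", "t", "1", "yes")
  int_cols <- c("dist_insomnia", "dist_early_waking", "dist_night_waking")
  for (cl in int_cols) co[[cl]] <- suppressWarnings(as.integer(co[[cl]]))
  # outcomes may be continuous (unclamped generator) or 0-7 survey integers
  for (cl in c("outcome_cig", "outcome_alc")) {
    v <- suppressWarnings(as.numeric(co[[cl]]))
    whole <- is.na(v) | v == floor(v)
    co[[cl]] <- if (all(whole)) as.integer(v) else v
  }
  # numeric time-varying covariates stay numeric if they parse cleanly
  for (cl in intersect(c(schema$time_varying, schema$time_invariant), names(co))) {
    num <- suppressWarnings(as.numeric(co[[cl]]))
    if (!anyNA(num[!is.na(co[[cl]])])) co[[cl]] <- num
  }
  co <- as_cohort(co, time_invariant = intersect(schema$time_invariant, names(co)),
                  time_varying = intersect(schema$time_varying, names(co)))
  validate_cohort(co)
  co
}

#' Mark a tibble as a cohort
#'
#' Attaches covariate-role attributes used by downstream model builders.
#' @param x A tibble with the canonical cohort columns.
#' @param time_invariant,time_varying Covariate column names by role.
#' @return The tibble with cohort attributes.
#' @export
as_cohort <- function(x,
                      time_invariant = attr(x, "time_invariant"),
                      time_varying = attr(x, "time_varying")) {
  x <- tibble::as_tibble(x)
  attr(x, "time_invariant") <- time_invariant %||% character()
  attr(x, "time_varying") <- time_varying %||% character()
  attr(x, "wave_order") <- wave_order()
  x
}

#' Validate cohort invariants
#'
#' Checks: known wave labels; exactly one row per (person, wave); every
#' person has a wave-1 record; disturbance items in 0--4; outcomes in 0--7
#' and present only at wave 9; unobserved waves carry no wave-specific data;
#' clock strings parseable.
#'
#' @param cohort A cohort tibble.
#' @return Invisibly, the cohort (errors on violation).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_core_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_wave <- setdiff(unique(cohort$wave), wave_order())
  if (length(bad_wave)) {
    stop("unknown wave label(s): ", paste(bad_wave, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(cohort[c("person_id", "wave")])
  if (any(dup)) {
    d <- cohort[dup, c("person_id", "wave")][1, ]
    stop("duplicate (person, wave) record: (", d$person_id, ", ", d$wave, ")",
         call. = FALSE)
  }
  has_w1 <- tapply(cohort$wave == 1L, cohort$person_id, any)
  if (!all(has_w1)) {
    stop("person(s) without a wave-1 record: ",
         paste(head(names(has_w1)[!has_w1], 5), collapse = ", "), call. = FALSE)
  }
  for (item in c("dist_insomnia", "dist_early_waking", "dist_night_waking")) {
    v <- cohort[[item]]
    bad <- which(!is.na(v) & (v < 0 | v > 4))
    if (length(bad)) {
      stop("disturbance item '", item, "' out of range 0-4 at row ", bad[1],
           call. = FALSE)
    }
  }
  for (oc in c("outcome_cig", "outcome_alc")) {
    v <- cohort[[oc]]
    # the 0-7 survey frequency scale applies to integer-coded outcomes;
    # continuous outcomes (generator clamping disabled) are exempt
    if (is.integer(v)) {
      bad <- which(!is.na(v) & (v < 0 | v > 7))
      if (length(bad)) {
        stop("outcome '", oc, "' out of frequency range 0-7 at row ", bad[1],
             call. = FALSE)
      }
    }
    off_wave <- which(!is.na(v) & cohort$wave != 9L)
    if (length(off_wave)) {
      stop("outcome '", oc, "' present outside wave 9 at row ", off_wave[1],
           call. = FALSE)
    }
  }
  wave_fields <- c("weekday_bed", "weekday_wake", "weekend_bed", "weekend_wake",
                   "dist_insomnia", "dist_early_waking", "dist_night_waking")
  unobs <- !cohort$observed
  if (any(unobs)) {
    leaked <- vapply(wave_fields, function(f) any(!is.na(cohort[[f]][unobs])),
                     logical(1))
    if (any(leaked)) {
      stop("unobserved rows carry wave-specific data in: ",
           paste(wave_fields[leaked], collapse = ", "), call. = FALSE)
    }
  }
  for (f in c("weekday_bed", "weekday_wake", "weekend_bed", "weekend_wake")) {
    parse_clock(cohort[[f]])  # errors on malformed strings
  }
  invisible(cohort)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort]: one row per person-wave, missing values as
#' empty cells. Round-trips field-identically for a conforming cohort.
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Apply baseline exclusion rules
#'
#' Drops (1) persons who had already smoked or drunk alcohol at wave 1 and
#' (2) persons missing either wave-9 substance-use outcome. Removal counts
#' per rule are reported via `message()` and attached as attribute
#' `exclusion_counts`. Idempotent.
#'
#' @param cohort A cohort tibble. Baseline substance use is read from the
#'   `self_substance` column at wave 1 (values "yes"/1 mean prior use).
#' @param quiet Suppress the per-rule messages.
#' @return The filtered cohort.
#' @export
apply_baseline_exclusions <- function(cohort, quiet = FALSE) {
  w1 <- cohort[cohort$wave == 1L, ]
  baseline_user <- rep(FALSE, nrow(w1))
  if ("self_substance" %in% names(cohort)) {
    v <- w1$self_substance
    baseline_user <- !is.na(v) & (v %in% c("yes", "Yes", "1") | (is.numeric(v) & v == 1))
  }
  users <- w1$person_id[baseline_user]
  w9 <- cohort[cohort$wave == 9L, ]
  no_outcome <- w9$person_id[is.na(w9$outcome_cig) | is.na(w9$outcome_alc)]
  # persons without any wave-9 row also lack outcomes
  no_w9 <- setdiff(unique(cohort$person_id), w9$person_id)
  no_outcome <- union(no_outcome, no_w9)
  n_users <- length(unique(users))
  n_noout <- length(setdiff(no_outcome, users))
  if (!quiet) {
    message("excluded ", n_users, " wave-1 substance users; ",
            n_noout, " further with incomplete wave-9 outcomes")
  }
  keep <- !(cohort$person_id %in% c(users, no_outcome))
  out <- as_cohort(cohort[keep, ],
                   time_invariant = attr(cohort, "time_invariant"),
                   time_varying = attr(cohort, "time_varying"))
  attr(out, "exclusion_counts") <- c(baseline_use = n_users,
                                     missing_outcome = n_noout)
  out
}

#' Missing-indicator coding for categorical covariates
#'
#' Item non-response in nominal/ordinal covariates is handled by adding an
#' explicit "MISSING" level rather than dropping rows, so every person keeps
#' their record and the missingness pattern itself enters the model. Values
#' that are present are never altered and no rows are removed.
#'
#' @param cohort A cohort tibble.
#' @param variables Character vector of covariate columns to encode. Each
#'   must be categorical (character/factor/logical) or a numeric column with
#'   few distinct values declared via `declare_categorical`.
#' @param declare_categorical Numeric columns listed here are treated as
#'   categorical (their distinct values become levels). An undeclared
#'   continuous column is an error.
#' @param level Label used for the missing category.
#' @return The cohort with each listed variable converted to a factor
#'   carrying the extra level.
#' @export
encode_missing_indicator <- function(cohort, variables,
                                     declare_categorical = character(),
                                     level = "MISSING") {
  for (v in variables) {
    if (!v %in% names(cohort)) stop("no such column: ", v, call. = FALSE)
    x <- cohort[[v]]
    if (is.numeric(x) && !v %in% declare_categorical) {
      stop("'", v, "' is numeric and may be continuous; list it in ",
           "`declare_categorical` to use its values as levels",
           call. = FALSE)
    }
    f <- factor(x)
    f <- factor(f, levels = c(levels(f), level))
    f[is.na(f)] <- level
    cohort[[v]] <- f
  }
  cohort
}
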