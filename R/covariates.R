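# Index dates, hypertension classification and windowed summary statistics.
# The per-subject anchor ("index date") is the first POAG ICD-9 date for case
# tiers and the last clinic-visit CPT date for controls; the covariate window
# is a centered two-year interval: |date - index| <= covariate_window_days.

#' Derive per-subject index dates
#'
#' Case tiers anchor on the earliest POAG ICD-9 (365.11) event date
#' (`index_kind = "diagnosis"`); controls anchor on the latest CPT event
#' date (`index_kind = "last_clinic_visit"`).  Other statuses carry no
#' index and are absent from the result.
#'
#' @param cohort An `emr_cohort`.
#' @param assignments Result of [run_phenotyping()].
#' @param lexicon A `poag_lexicon`.
#' @return Tibble: `subject_id`, `index_date`, `index_kind`.
#' @export
index_dates <- function(cohort, assignments, lexicon = default_lexicon()) {
  case_ids <- assignments$subject_id[
    assignments$status %in% c("case_definite", "case_potential",
                              "case_indeterminate")]
  control_ids <- assignments$subject_id[assignments$status == "control"]

  poag_ev <- filter(cohort$coded_events, .data$code_system == "ICD9",
                    .data$code == lexicon$poag_icd9,
                    .data$subject_id %in% case_ids)
  missing_cases <- setdiff(case_ids, poag_ev$subject_id)
  if (length(missing_cases) > 0) {
    abort(sprintf("case subject(s) without a POAG ICD-9 event: %s",
                  paste(missing_cases, collapse = ", ")))
  }
  empty_idx <- tibble(subject_id = character(),
                      index_date = as.Date(character()))
  cases <- if (nrow(poag_ev) == 0) empty_idx else poag_ev %>%
    group_by(.data$subject_id) %>%
    summarise(index_date = min(.data$event_date))
  cases$index_kind <- rep("diagnosis", nrow(cases))

  cpt_ev <- filter(cohort$coded_events, .data$code_system == "CPT",
                   .data$subject_id %in% control_ids)
  controls <- if (nrow(cpt_ev) == 0) empty_idx else cpt_ev %>%
    group_by(.data$subject_id) %>%
    summarise(index_date = max(.data$event_date))
  controls$index_kind <- rep("last_clinic_visit", nrow(controls))

  bind_rows(cases, controls) %>% arrange(.data$subject_id)
}

in_window <- function(dates, index, window_days) {
  abs(as.integer(dates - index)) <= window_days
}

#' Classify a subject as hypertensive around an index date
#'
#' True when, within the covariate window of the index date, any systolic
#' blood pressure exceeds the systolic threshold (strictly above
#' 140 mm Hg by default), any diastolic exceeds the diastolic threshold
#' (strictly above 90 mm Hg), or any hypertension medication is mentioned.  Any
#' single qualifying value counts; same-day readings are not aggregated.
#'
#' @param measurements One subject's measurements tibble.
#' @param medications One subject's medications tibble.
#' @param index Index `Date`.
#' @param lexicon A `poag_lexicon`.
#' @return Logical scalar.
#' @export
is_hypertensive <- function(measurements, medications, index,
                            lexicon = default_lexicon()) {
  w <- lexicon$covariate_window_days
  sbp <- filter(measurements, .data$kind == "sbp",
                in_window(.data$measure_date, index, w))
  dbp <- filter(measurements, .data$kind == "dbp",
                in_window(.data$measure_date, index, w))
  meds <- match_medications(medications, lexicon$hypertension_medications)
  meds <- filter(meds, in_window(.data$mention_date, index, w))
  any(sbp$value > lexicon$sbp_threshold) ||
    any(dbp$value > lexicon$dbp_threshold) ||
    nrow(meds) > 0
}

#' Median of one measurement kind within the covariate window
#'
#' Median of all values of `kind` whose dates lie within the window around
#' `index`; an even count yields the mean of the two middle values; no
#' in-window values yields `NA`.
#'
#' @param measurements One subject's measurements tibble.
#' @param kind Measurement kind (e.g. `"bmi"`, `"sbp"`).
#' @param index Index `Date`.
#' @param lexicon A `poag_lexicon`.
#' @return Numeric scalar or `NA_real_`.
#' @export
windowed_median <- function(measurements, kind, index,
                            lexicon = default_lexicon()) {
  v <- measurements$value[measurements$kind == kind &
                            in_window(measurements$measure_date, index,
                                      lexicon$covariate_window_days)]
  if (length(v) == 0) return(NA_real_)
  stats::median(v)
}

#' Derive the per-subject covariate profile
#'
#' For every case-tier and control subject: index date and kind, age at
#' index, sex, hypertension status, and the windowed median of each
#' measurement kind present in the record.
#'
#' @param cohort An `emr_cohort`.
#' @param assignments Result of [run_phenotyping()].
#' @param lexicon A `poag_lexicon`.
#' @return Tibble: `subject_id`, `status`, `index_date`, `index_kind`,
#'   `age_at_index`, `sex`, `hypertensive`, then one column per
#'   measurement kind (`NA` when no in-window values exist).
#' @export
derive_covariates <- function(cohort, assignments,
                              lexicon = default_lexicon()) {
  idx <- index_dates(cohort, assignments, lexicon)
  demo <- cohort$demographics
  kinds <- MEASUREMENT_KINDS

  profiles <- purrr::map(seq_len(nrow(idx)), function(i) {
    sid <- idx$subject_id[i]
    index <- idx$index_date[i]
    d <- demo[demo$subject_id == sid, ]
    meas <- filter(cohort$measurements, .data$subject_id == sid)
    meds <- filter(cohort$medications, .data$subject_id == sid)
    meds_w <- stats::setNames(
      as.list(map_dbl(kinds, ~ windowed_median(meas, .x, index, lexicon))),
      kinds
    )
    age <- as.integer(format(index, "%Y")) - d$birth_year
    dplyr::bind_cols(
      tibble(
        subject_id = sid,
        index_date = index,
        index_kind = idx$index_kind[i],
        age_at_index = age,
        sex = d$sex,
        hypertensive = is_hypertensive(meas, meds, index, lexicon)
      ),
      as_tibble(meds_w)
    )
  })
  profiles <- list_rbind(profiles)
  if (nrow(profiles) > 0 && any(profiles$age_at_index < 0)) {
    abort("age_at_index is negative for at least one subject")
  }
  st <- tibble(subject_id = assignments$subject_id,
               status = as.character(assignments$status))
  left_join(profiles, st, by = "subject_id") %>%
    select("subject_id", "status", dplyr::everything())
}

#' Summarize a cohort's covariate profiles per status tier
#'
#' Produces a study-characteristics table: per status, the subject count,
#' median age at index, percent female (over subjects with known sex),
#' percent hypertensive, and the median across subjects of each
#' per-subject windowed median, with non-missing denominators.
#'
#' @param profiles Result of [derive_covariates()].
#' @return Tibble, one row per status.
#' @export
summarize_cohort <- function(profiles) {
  kinds <- intersect(MEASUREMENT_KINDS, names(profiles))
  base <- profiles %>%
    group_by(.data$status) %>%
    summarise(
      n = dplyr::n(),
      median_age = stats::median(.data$age_at_index),
      n_sex_known = sum(.data$sex != "unknown"),
      pct_female = 100 * sum(.data$sex == "female") /
        pmax(1L, sum(.data$sex != "unknown")),
      pct_hypertensive = 100 * mean(.data$hypertensive),
      .groups = "drop"
    )
  med_cols <- profiles %>%
    group_by(.data$status) %>%
    summarise(
      dplyr::across(dplyr::all_of(kinds),
                    list(median = ~ stats::median(.x, na.rm = TRUE),
                         n = ~ sum(!is.na(.x)))),
      .groups = "drop"
    )
  left_join(base, med_cols, by = "status")
}

#' Render a cohort summary as aligned text
#'
#' @param summary Result of [summarize_cohort()].
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_summary <- function(summary) {
  df <- as.data.frame(summary)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 1))
  lines <- utils::capture.output(print(df, row.names = FALSE))
  cat(lines, sep = "\n")
  invisible(lines)
}
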