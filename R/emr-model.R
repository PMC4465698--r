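# Domain model for longitudinal, de-identified EMR data: one cohort is five
# tibbles (demographics, coded events, medication mentions, measurements,
# documents) keyed by an opaque subject_id.  Birth dates are year-resolution
# (the de-identified source supplies year only); event dates are day-level
# ISO-8601 calendar dates.

SEX_LEVELS <- c("female", "male", "unknown")
CODE_SYSTEMS <- c("ICD9", "CPT")
MEASUREMENT_KINDS <- c(
  "sbp", "dbp", "height", "weight", "bmi",
  "total_cholesterol", "hdl", "ldl", "triglycerides"
)
DOC_TYPES <- c("ophtho_letter", "surgical_report", "problem_list", "clinic_note")

# plausibility bounds per measurement kind (conventional units: mm Hg, cm, kg,
# kg/m2, mg/dL); violations warn at load, they never drop rows
MEASUREMENT_BOUNDS <- list(
  sbp = c(50, 300), dbp = c(20, 200),
  height = c(50, 250), weight = c(20, 350), bmi = c(10, 100),
  total_cholesterol = c(50, 600), hdl = c(5, 200), ldl = c(10, 400),
  triglycerides = c(10, 2000)
)

empty_demographics <- function() {
  tibble(
    subject_id = character(), birth_year = integer(),
    sex = character(), race_ethnicity = character()
  )
}

empty_coded_events <- function() {
  tibble(
    subject_id = character(), code_system = character(), code = character(),
    event_date = as.Date(character()), source_document_id = character()
  )
}

empty_medications <- function() {
  tibble(
    subject_id = character(), drug_name = character(),
    mention_date = as.Date(character())
  )
}

empty_measurements <- function() {
  tibble(
    subject_id = character(), kind = character(), value = double(),
    measure_date = as.Date(character())
  )
}

empty_documents <- function() {
  tibble(
    document_id = character(), subject_id = character(), doc_type = character(),
    doc_date = as.Date(character()), text = character()
  )
}

#' Assemble a typed EMR cohort
#'
#' Bundles the five per-row tables of a longitudinal EMR cohort —
#' demographics, coded billing events (ICD-9 / CPT), medication mentions,
#' vital-sign and laboratory measurements, and dated free-text clinical
#' documents — into a validated `emr_cohort` object.  All child tables must
#' reference subjects present in `demographics`.
#'
#' @param demographics Tibble with columns `subject_id`, `birth_year`
#'   (integer year; only birth *year* is modeled, so ages are integer year
#'   differences), `sex` (`"female"`, `"male"`, `"unknown"`), and
#'   `race_ethnicity` (free-form label).
#' @param coded_events Tibble with `subject_id`, `code_system` (`"ICD9"` or
#'   `"CPT"`), `code` (verbatim string, e.g. `"365.11"` or `"92014"`),
#'   `event_date` (Date), and optional `source_document_id`.
#' @param medications Tibble with `subject_id`, `drug_name` (lowercase),
#'   `mention_date` (Date).
#' @param measurements Tibble with `subject_id`, `kind` (one of
#'   `r paste0('\x60', MEASUREMENT_KINDS, '\x60', collapse = ", ")`),
#'   `value` (positive, conventional units), `measure_date` (Date).
#' @param documents Tibble with `document_id`, `subject_id`, `doc_type`
#'   (`"ophtho_letter"`, `"surgical_report"`, `"problem_list"`,
#'   `"clinic_note"`), `doc_date` (Date), `text` (may be empty).
#'
#' @return An `emr_cohort`: a named list of the five validated tibbles.
#' @examples
#' demo <- tibble::tibble(
#'   subject_id = "S1", birth_year = 1950L,
#'   sex = "female", race_ethnicity = "African American"
#' )
#' ev <- tibble::tibble(
#'   subject_id = "S1", code_system = "ICD9", code = "365.11",
#'   event_date = as.Date("2010-02-01"), source_document_id = NA_character_
#' )
#' emr_cohort(demographics = demo, coded_events = ev)
#' @export
emr_cohort <- function(demographics,
                       coded_events = NULL,
                       medications = NULL,
                       measurements = NULL,
                       documents = NULL) {
  demographics <- as_tibble(demographics)
  coded_events <- as_tibble(coded_events %||% empty_coded_events())
  medications <- as_tibble(medications %||% empty_medications())
  measurements <- as_tibble(measurements %||% empty_measurements())
  documents <- as_tibble(documents %||% empty_documents())

  if (!"source_document_id" %in% names(coded_events)) {
    coded_events$source_document_id <- rep(NA_character_, nrow(coded_events))
  }
  demographics$birth_year <- as.integer(demographics$birth_year)

  validate_cohort_tables(demographics, coded_events, medications,
                         measurements, documents)

  structure(
    list(
      demographics = demographics,
      coded_events = coded_events,
      medications = medications,
      measurements = measurements,
      documents = documents
    ),
    class = "emr_cohort"
  )
}

validate_cohort_tables <- function(demographics, coded_events, medications,
                                   measurements, documents) {
  need <- function(tbl, cols, what) {
    missing <- setdiff(cols, names(tbl))
    if (length(missing) > 0) {
      abort(sprintf("%s is missing column(s): %s", what,
                    paste(missing, collapse = ", ")))
    }
  }
  need(demographics, c("subject_id", "birth_year", "sex", "race_ethnicity"),
       "demographics")
  need(coded_events, c("subject_id", "code_system", "code", "event_date"),
       "coded_events")
  need(medications, c("subject_id", "drug_name", "mention_date"), "medications")
  need(measurements, c("subject_id", "kind", "value", "measure_date"),
       "measurements")
  need(documents, c("document_id", "subject_id", "doc_type", "doc_date", "text"),
       "documents")

  if (anyDuplicated(demographics$subject_id)) {
    abort("duplicate subject_id in demographics; subject ids must be unique")
  }
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  bad_year <- !is.na(demographics$birth_year) &
    (demographics$birth_year < 1880L | demographics$birth_year > this_year)
  if (any(bad_year)) {
    abort(sprintf("implausible birth_year for subject(s): %s",
                  paste(demographics$subject_id[bad_year], collapse = ", ")))
  }
  if (!all(demographics$sex %in% SEX_LEVELS)) {
    abort(sprintf("sex must be one of: %s", paste(SEX_LEVELS, collapse = ", ")))
  }
  if (!all(coded_events$code_system %in% CODE_SYSTEMS)) {
    abort("code_system must be 'ICD9' or 'CPT'")
  }
  icd <- coded_events$code[coded_events$code_system == "ICD9"]
  if (length(icd) > 0 && !all(grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", icd))) {
    abort("ICD9 codes must be three digits with an optional 1-2 digit decimal")
  }
  cpt <- coded_events$code[coded_events$code_system == "CPT"]
  if (length(cpt) > 0 && !all(grepl("^[0-9]{5}$", cpt))) {
    abort("CPT codes must be exactly five digits")
  }
  for (col_tbl in list(
    list(coded_events$event_date, "coded_events$event_date"),
    list(medications$mention_date, "medications$mention_date"),
    list(measurements$measure_date, "measurements$measure_date"),
    list(documents$doc_date, "documents$doc_date")
  )) {
    if (!inherits(col_tbl[[1]], "Date")) {
      abort(sprintf("%s must be a Date column", col_tbl[[2]]))
    }
    if (anyNA(col_tbl[[1]])) {
      abort(sprintf("%s contains missing dates", col_tbl[[2]]))
    }
  }
  if (nrow(measurements) > 0) {
    if (!all(measurements$kind %in% MEASUREMENT_KINDS)) {
      abort(sprintf("measurement kind must be one of: %s",
                    paste(MEASUREMENT_KINDS, collapse = ", ")))
    }
    if (any(measurements$value <= 0)) {
      abort("measurement values must be positive")
    }
    oob <- purrr::map2_lgl(measurements$kind, measurements$value, function(k, v) {
      b <- MEASUREMENT_BOUNDS[[k]]
      v < b[1] || v > b[2]
    })
    if (any(oob)) {
      warn(sprintf("%d measurement value(s) outside plausibility bounds (kept)",
                   sum(oob)))
    }
  }
  if (nrow(documents) > 0) {
    if (!all(documents$doc_type %in% DOC_TYPES)) {
      abort(sprintf("doc_type must be one of: %s",
                    paste(DOC_TYPES, collapse = ", ")))
    }
    if (anyDuplicated(documents$document_id)) {
      abort("duplicate document_id in documents")
    }
  }
  known <- demographics$subject_id
  for (child in list(
    list(coded_events$subject_id, "coded_events"),
    list(medications$subject_id, "medications"),
    list(measurements$subject_id, "measurements"),
    list(documents$subject_id, "documents")
  )) {
    orphan <- setdiff(unique(child[[1]]), known)
    if (length(orphan) > 0) {
      abort(sprintf("%s references unknown subject(s): %s", child[[2]],
                    paste(orphan, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("<emr_cohort>\n")
  cat(sprintf("  subjects:     %d\n", nrow(x$demographics)))
  cat(sprintf("  coded events: %d (ICD9 %d, CPT %d)\n",
              nrow(x$coded_events),
              sum(x$coded_events$code_system == "ICD9"),
              sum(x$coded_events$code_system == "CPT")))
  cat(sprintf("  medications:  %d\n", nrow(x$medications)))
  cat(sprintf("  measurements: %d\n", nrow(x$measurements)))
  cat(sprintf("  documents:    %d\n", nrow(x$documents)))
  rep <- attr(x, "load_report")
  if (!is.null(rep) && nrow(rep) > 0) {
    cat(sprintf("  quarantined rows at load: %d\n", nrow(rep)))
  }
  invisible(x)
}

#' Compute age in whole years at a reference date
#'
#' Only birth *year* is available in the de-identified record, so age is the
#' integer year difference between the reference date and the birth year.
#'
#' @param demographics Demographics tibble (or an `emr_cohort`).
#' @param on_date Reference `Date` (scalar).
#' @return Integer vector of ages, one per demographics row, named by
#'   `subject_id`.
#' @examples
#' demo <- tibble::tibble(
#'   subject_id = "S1", birth_year = 1950L,
#'   sex = "unknown", race_ethnicity = NA_character_
#' )
#' age_at(demo, as.Date("2013-03-20")) # 63
#' @export
age_at <- function(demographics, on_date) {
  if (inherits(demographics, "emr_cohort")) {
    demographics <- demographics$demographics
  }
  stopifnot(inherits(on_date, "Date"), length(on_date) == 1)
  age <- as.integer(format(on_date, "%Y")) - demographics$birth_year
  if (any(age < 0, na.rm = TRUE)) {
    abort("reference date precedes birth year for at least one subject")
  }
  stats::setNames(age, demographics$subject_id)
}

## ---- cohort directory dialect -----------------------------------------------
## One directory: demographics.csv, coded_events.csv, medications.csv,
## measurements.csv (UTF-8 CSV with header), documents.jsonl (one JSON object
## per line: document_id, subject_id, doc_type, doc_date, text).

cohort_csv_specs <- function() {
  list(
    demographics = list(
      file = "demographics.csv",
      cols = c("subject_id", "birth_year", "sex", "race_ethnicity"),
      date_cols = character()
    ),
    coded_events = list(
      file = "coded_events.csv",
      cols = c("subject_id", "code_system", "code", "event_date",
               "source_document_id"),
      date_cols = "event_date"
    ),
    medications = list(
      file = "medications.csv",
      cols = c("subject_id", "drug_name", "mention_date"),
      date_cols = "mention_date"
    ),
    measurements = list(
      file = "measurements.csv",
      cols = c("subject_id", "kind", "value", "measure_date"),
      date_cols = "measure_date"
    )
  )
}

parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

#' Read a cohort directory into a typed `emr_cohort`
#'
#' Reads the cohort file dialect: four UTF-8 CSV files
#' (`demographics.csv`, `coded_events.csv`, `medications.csv`,
#' `measurements.csv`) plus `documents.jsonl` (one JSON object per document).
#' Rows whose dates fail to parse as ISO-8601 are quarantined into a load
#' report — never silently dropped; the report is attached as the
#' `"load_report"` attribute (see [load_report()]) and optionally written to
#' `report_path` as text.
#'
#' @param path Directory containing the cohort files.
#' @param report_path Optional path for a plain-text load report listing
#'   quarantined rows.
#' @return An [emr_cohort()] with attribute `load_report`.
#' @export
read_cohort <- function(path, report_path = NULL) {
  specs <- cohort_csv_specs()
  for (s in specs) {
    if (!file.exists(file.path(path, s$file))) {
      abort(sprintf("required cohort file missing: %s", s$file))
    }
  }
  if (!file.exists(file.path(path, "documents.jsonl"))) {
    abort("required cohort file missing: documents.jsonl")
  }

  quarantine <- list()
  tables <- list()
  for (nm in names(specs)) {
    s <- specs[[nm]]
    raw <- readr::read_csv(file.path(path, s$file),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    missing <- setdiff(setdiff(s$cols, "source_document_id"), names(raw))
    if (length(missing) > 0) {
      abort(sprintf("%s is missing column(s): %s", s$file,
                    paste(missing, collapse = ", ")))
    }
    if (!"source_document_id" %in% names(raw) && nm == "coded_events") {
      raw$source_document_id <- NA_character_
    }
    bad <- rep(FALSE, nrow(raw))
    for (dc in s$date_cols) {
      parsed <- parse_iso_date(raw[[dc]])
      bad <- bad | is.na(parsed)
      raw[[dc]] <- parsed
    }
    if (any(bad)) {
      quarantine[[nm]] <- tibble(
        file = s$file,
        row = which(bad),
        subject_id = raw$subject_id[bad],
        reason = "malformed date"
      )
      raw <- raw[!bad, , drop = FALSE]
    }
    tables[[nm]] <- raw
  }
  tables$demographics$birth_year <- as.integer(tables$demographics$birth_year)
  if (nrow(tables$measurements) > 0) {
    tables$measurements$value <- as.numeric(tables$measurements$value)
  } else {
    tables$measurements$value <- double()
  }

  doc_lines <- readLines(file.path(path, "documents.jsonl"), encoding = "UTF-8")
  doc_lines <- doc_lines[nzchar(trimws(doc_lines))]
  docs <- purrr::map(doc_lines, function(l) {
    obj <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(obj)) return(list(bad = l, reason = "malformed JSON"))
    d <- parse_iso_date(as.character(obj$doc_date %||% NA_character_))
    if (is.na(d)) return(list(bad = l, reason = "malformed date"))
    tibble(
      document_id = as.character(obj$document_id),
      subject_id = as.character(obj$subject_id),
      doc_type = as.character(obj$doc_type),
      doc_date = d,
      text = as.character(obj$text %||% "")
    )
  })
  bad_docs <- purrr::keep(docs, ~ !is.data.frame(.x))
  good_docs <- purrr::keep(docs, is.data.frame)
  documents <- if (length(good_docs) > 0) list_rbind(good_docs) else empty_documents()
  if (length(bad_docs) > 0) {
    quarantine$documents <- tibble(
      file = "documents.jsonl",
      row = which(!purrr::map_lgl(docs, is.data.frame)),
      subject_id = NA_character_,
      reason = map_chr(bad_docs, "reason")
    )
  }

  report <- if (length(quarantine) > 0) list_rbind(quarantine) else
    tibble(file = character(), row = integer(), subject_id = character(),
           reason = character())

  cohort <- emr_cohort(
    demographics = tables$demographics,
    coded_events = tables$coded_events,
    medications = tables$medications,
    measurements = tables$measurements,
    documents = documents
  )
  attr(cohort, "load_report") <- report
  if (!is.null(report_path)) {
    lines <- c(
      sprintf("cohort load report: %d row(s) quarantined", nrow(report)),
      if (nrow(report) > 0) {
        sprintf("%s row %d subject %s: %s", report$file, report$row,
                ifelse(is.na(report$subject_id), "?", report$subject_id),
                report$reason)
      }
    )
    writeLines(lines, report_path)
  }
  cohort
}

#' Retrieve the quarantine report attached by [read_cohort()]
#'
#' @param cohort An `emr_cohort`.
#' @return Tibble with one row per quarantined input row (`file`, `row`,
#'   `subject_id`, `reason`); zero rows when every input row parsed.
#' @export
load_report <- function(cohort) {
  attr(cohort, "load_report") %||%
    tibble(file = character(), row = integer(), subject_id = character(),
           reason = character())
}

#' Write an `emr_cohort` back to the cohort directory dialect
#'
#' Inverse of [read_cohort()]: writes the four CSV files and
#' `documents.jsonl`.  Round-tripping preserves typed content field-for-field
#' (dates are normalized to ISO-8601).
#'
#' @param cohort An `emr_cohort`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "emr_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  specs <- cohort_csv_specs()
  for (nm in names(specs)) {
    tbl <- cohort[[nm]]
    readr::write_csv(tbl, file.path(path, specs[[nm]]$file), progress = FALSE)
  }
  docs <- cohort$documents
  lines <- purrr::pmap_chr(docs, function(document_id, subject_id, doc_type,
                                          doc_date, text) {
    jsonlite::toJSON(
      list(document_id = document_id, subject_id = subject_id,
           doc_type = doc_type, doc_date = format(doc_date, "%Y-%m-%d"),
           text = text),
      auto_unbox = TRUE
    )
  })
  writeLines(lines, file.path(path, "documents.jsonl"), useBytes = TRUE)
  invisible(path)
}

#' Extract one subject's slice of a cohort
#'
#' @param cohort An `emr_cohort`.
#' @param subject_id Single subject id.
#' @return An `emr_cohort` containing just that subject.
#' @export
subject_record <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "emr_cohort"), length(subject_id) == 1)
  sid <- subject_id
  emr_cohort(
    demographics = filter(cohort$demographics, .data$subject_id == sid),
    coded_events = filter(cohort$coded_events, .data$subject_id == sid),
    medications = filter(cohort$medications, .data$subject_id == sid),
    measurements = filter(cohort$measurements, .data$subject_id == sid),
    documents = filter(cohort$documents, .data$subject_id == sid)
  )
}
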