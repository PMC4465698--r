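# Free-text mining over clinical documents: term search, diagnosis-statement
# detection, and cup-to-disc ratio (CDR) extraction with laterality.
# Matching is case-insensitive; extraction is deterministic (same documents
# in, same matches out, in document order).

# guard a literal so it matches only at word boundaries; [:alnum:] lookarounds
# rather than \b because clinical shorthand ("o.d.") mixes in punctuation
word_bounded <- function(literal) {
  sprintf("(?<![[:alnum:]])%s(?![[:alnum:]])",
          gsub("([][{}()*+?.\\^$|])", "\\\\\\1", literal))
}

#' Search documents for a list of terms
#'
#' Case-insensitive substring (or whole-word) search over document text.
#' Every occurrence of every term is reported, including overlapping terms;
#' matches come back in document order, then by character offset.
#'
#' @param documents Documents tibble (as in [emr_cohort()]) or an
#'   `emr_cohort`.
#' @param terms Character vector of lowercase search terms.
#' @param whole_word If `TRUE`, a match must be bounded by non-alphanumeric
#'   characters on both sides ("vision" does not match inside "visionary").
#' @return Tibble with `document_id`, `subject_id`, `term`, `char_offset`
#'   (1-based), `doc_date`.
#' @examples
#' docs <- tibble::tibble(
#'   document_id = "D1", subject_id = "S1", doc_type = "clinic_note",
#'   doc_date = as.Date("2012-01-01"), text = "ophthalmology consult re: vision"
#' )
#' find_terms(docs, c("ophth", "vision"))
#' @export
find_terms <- function(documents, terms, whole_word = FALSE) {
  if (inherits(documents, "emr_cohort")) documents <- documents$documents
  stopifnot(is.character(terms), all(terms == tolower(terms)))
  if (nrow(documents) == 0 || length(terms) == 0) {
    return(tibble(document_id = character(), subject_id = character(),
                  term = character(), char_offset = integer(),
                  doc_date = as.Date(character())))
  }
  out <- pmap(documents[c("document_id", "subject_id", "doc_date", "text")],
    function(document_id, subject_id, doc_date, text) {
      low <- tolower(text)
      hits <- purrr::map(terms, function(tm) {
        pos <- if (whole_word) {
          gregexpr(word_bounded(tm), low, perl = TRUE)[[1]]
        } else {
          gregexpr(tm, low, fixed = TRUE)[[1]]
        }
        if (pos[1] == -1L) return(NULL)
        tibble(document_id = document_id, subject_id = subject_id,
               term = tm, char_offset = as.integer(pos), doc_date = doc_date)
      })
      hits <- purrr::compact(hits)
      if (length(hits) == 0) NULL else list_rbind(hits)
    })
  out <- purrr::compact(out)
  if (length(out) == 0) {
    return(tibble(document_id = character(), subject_id = character(),
                  term = character(), char_offset = integer(),
                  doc_date = as.Date(character())))
  }
  res <- list_rbind(out)
  # document order is input row order; within a document, by offset
  res$.doc_ord <- match(res$document_id, documents$document_id)
  res <- arrange(res, .data$.doc_ord, .data$char_offset, .data$term)
  res$.doc_ord <- NULL
  res
}

## ---- cup-to-disc ratio extraction -------------------------------------------

# CDR key phrases: "CDR", "C/D", "cup-to-disc ratio", "cup-to-disk",
# "cup to disc/disk (ratio)" -- hyphen/space tolerant, case-insensitive
CDR_PHRASE_RX <- paste0(
  "(?i)(?:",
  "(?<![[:alnum:]])c\\s*/\\s*d(?![[:alnum:]])",
  "|(?<![[:alnum:]])cdr(?![[:alnum:]])",
  "|(?<![[:alnum:]])cup[\\s-]*to[\\s-]*dis[ck](?:[\\s-]*ratio)?(?![[:alnum:]])",
  ")"
)

CDR_NUMBER_RX <- "(?<![0-9.])(?:[0-9]+(?:\\.[0-9]+)?|\\.[0-9]+)"

OD_MARKER_RX <- "(?i)(?<![[:alnum:]])(?:o\\.?\\s?d\\.?|right\\s+eye)(?![[:alnum:]])"
OS_MARKER_RX <- "(?i)(?<![[:alnum:]])(?:o\\.?\\s?s\\.?|left\\s+eye)(?![[:alnum:]])"

# a second value is only paired with the first when the text between them is
# separators / laterality filler, never fresh prose
CDR_SEPARATOR_FILLER_RX <-
  "(?i)^(?:[\\s,;:/&-]|and|or|o\\.?d\\.?|o\\.?s\\.?|ou|right|left|eye|in|the)*$"

rx_all <- function(pattern, text, perl = TRUE) {
  m <- gregexpr(pattern, text, perl = perl)[[1]]
  if (m[1] == -1L) {
    return(tibble(start = integer(), end = integer(), match = character()))
  }
  tibble(start = as.integer(m),
         end = as.integer(m) + attr(m, "match.length") - 1L,
         match = regmatches(text, list(m))[[1]])
}

empty_cdr <- function() {
  tibble(subject_id = character(), document_id = character(),
         eye = character(), value = double(), axis = character(),
         doc_date = as.Date(character()), char_offset = integer(),
         source_span = character())
}

empty_cdr_report <- function() {
  tibble(subject_id = character(), document_id = character(),
         doc_date = as.Date(character()), reason = character(),
         span = character())
}

#' Extract cup-to-disc ratio measurements from clinical documents
#'
#' Scans each document for CDR key phrases (`CDR`, `C/D`, `cup-to-disc
#' ratio`, `cup-to-disk`, hyphen/space tolerant) followed within a bounded
#' character window by one or two decimal values in \[0, 1\].  Laterality is
#' assigned from the nearest `OD`/`O.D.`/"right eye" or `OS`/`O.S.`/"left
#' eye" marker; with exactly one marker of each eye near a value pair, the
#' pair is assigned positionally; otherwise the eye is `"unspecified"`.  An
#' axis tag (`horizontal`/`vertical`) is emitted when such a qualifier
#' adjoins the key phrase, else `"unspecified"` — reconciling
#' horizontal/vertical/quotient reporting styles is deliberately left to the
#' caller.  Every accepted value carries its verbatim source span.
#'
#' Phrase hits with no value in the window, and candidate values outside
#' \[0, 1\], are recorded in an extraction report attached as the
#' `"extraction_report"` attribute (see [cdr_extraction_report()]).
#'
#' @param documents Documents tibble or `emr_cohort`.
#' @param window Maximum characters between the key phrase and its value(s).
#' @return Tibble of measurements: `subject_id`, `document_id`, `eye`
#'   (`OD`/`OS`/`unspecified`), `value`, `axis`, `doc_date`, `char_offset`,
#'   `source_span`; with attribute `extraction_report`.
#' @examples
#' docs <- tibble::tibble(
#'   document_id = "D1", subject_id = "S1", doc_type = "ophtho_letter",
#'   doc_date = as.Date("2012-05-01"),
#'   text = "cup-to-disc ratio of 0.7 OD and 0.8 OS"
#' )
#' extract_cdr(docs)
#' @export
extract_cdr <- function(documents, window = 40) {
  if (inherits(documents, "emr_cohort")) documents <- documents$documents
  rows <- list()
  report <- list()

  for (i in seq_len(nrow(documents))) {
    doc <- documents[i, ]
    text <- doc$text
    if (is.na(text) || !nzchar(text)) next
    phrases <- rx_all(CDR_PHRASE_RX, text)
    if (nrow(phrases) == 0) next

    markers <- bind_rows(
      mutate(rx_all(OD_MARKER_RX, text), eye = "OD"),
      mutate(rx_all(OS_MARKER_RX, text), eye = "OS")
    ) %>% arrange(.data$start)

    taken_offsets <- integer() # value positions already claimed by a phrase hit

    for (p in seq_len(nrow(phrases))) {
      p_start <- phrases$start[p]
      p_end <- phrases$end[p]
      # window stops at the next phrase so hits never steal each other's values
      w_end <- min(nchar(text), p_end + window,
                   if (p < nrow(phrases)) phrases$start[p + 1] - 1L else Inf)
      win_text <- substr(text, p_end + 1L, w_end)

      axis <- cdr_axis_near(text, p_start, p_end)

      toks <- rx_all(CDR_NUMBER_RX, win_text)
      if (nrow(toks) > 0) {
        toks$start <- toks$start + p_end
        toks$end <- toks$end + p_end
      }
      if (nrow(toks) == 0) {
        report[[length(report) + 1]] <- tibble(
          subject_id = doc$subject_id, document_id = doc$document_id,
          doc_date = doc$doc_date, reason = "no_value_in_window",
          span = phrases$match[p]
        )
        next
      }
      toks <- toks[1:min(2, nrow(toks)), , drop = FALSE]
      if (nrow(toks) == 2) {
        between <- substr(text, toks$end[1] + 1L, toks$start[2] - 1L)
        if (!grepl(CDR_SEPARATOR_FILLER_RX, between, perl = TRUE)) {
          toks <- toks[1, , drop = FALSE]
        }
      }
      # phrase overlap ("cup-to-disc ratio (CDR) 0.7"): each value reported once
      toks <- toks[!(toks$start %in% taken_offsets), , drop = FALSE]
      if (nrow(toks) == 0) next
      taken_offsets <- c(taken_offsets, toks$start)

      vals <- as.numeric(toks$match)
      eyes <- cdr_assign_eyes(toks, markers, p_start, w_end)
      for (j in seq_len(nrow(toks))) {
        if (vals[j] < 0 || vals[j] > 1) {
          report[[length(report) + 1]] <- tibble(
            subject_id = doc$subject_id, document_id = doc$document_id,
            doc_date = doc$doc_date, reason = "value_out_of_range",
            span = substr(text, p_start, toks$end[j])
          )
          next
        }
        rows[[length(rows) + 1]] <- tibble(
          subject_id = doc$subject_id, document_id = doc$document_id,
          eye = eyes[j], value = vals[j], axis = axis,
          doc_date = doc$doc_date, char_offset = toks$start[j],
          source_span = substr(text, p_start, toks$end[j])
        )
      }
    }
  }

  res <- if (length(rows) > 0) list_rbind(rows) else empty_cdr()
  rep <- if (length(report) > 0) list_rbind(report) else empty_cdr_report()
  attr(res, "extraction_report") <- rep
  class(res) <- c("cdr_measurements", class(res))
  res
}

# axis qualifier adjoining the key phrase (looks 15 chars back / 12 ahead)
cdr_axis_near <- function(text, p_start, p_end) {
  before <- substr(text, max(1L, p_start - 15L), p_start - 1L)
  after <- substr(text, p_end + 1L, min(nchar(text), p_end + 12L))
  ctx <- paste(before, after)
  if (grepl("(?i)horizontal", ctx, perl = TRUE)) return("horizontal")
  if (grepl("(?i)vertical", ctx, perl = TRUE)) return("vertical")
  "unspecified"
}

# nearest-marker rule, then one-OD-one-OS positional fallback for pairs
cdr_assign_eyes <- function(toks, markers, span_start, span_end,
                            max_gap = 12L) {
  local_markers <- markers[markers$end >= max(1L, span_start - 30L) &
                             markers$start <= span_end + 12L, , drop = FALSE]
  eyes <- rep("unspecified", nrow(toks))
  for (j in seq_len(nrow(toks))) {
    if (nrow(local_markers) == 0) next
    gap <- pmax(local_markers$start - toks$end[j],
                toks$start[j] - local_markers$end)
    k <- which.min(gap)
    if (gap[k] <= max_gap) eyes[j] <- local_markers$eye[k]
  }
  if (nrow(toks) == 2 && all(eyes == "unspecified") &&
      sum(local_markers$eye == "OD") == 1 &&
      sum(local_markers$eye == "OS") == 1) {
    eyes <- local_markers$eye[order(local_markers$start)]
  }
  eyes
}

#' Retrieve the extraction report attached by [extract_cdr()]
#'
#' @param measurements Result of [extract_cdr()].
#' @return Tibble of phrase hits that yielded no usable value
#'   (`no_value_in_window`) or an out-of-range candidate
#'   (`value_out_of_range`).
#' @export
cdr_extraction_report <- function(measurements) {
  attr(measurements, "extraction_report") %||% empty_cdr_report()
}

#' Keep the most recent CDR measurement per eye
#'
#' For each subject (when a `subject_id` column is present) and each eye
#' independently, returns the measurement with the latest document date.
#' Ties on date are broken by the latest position within the document, then
#' by last in input order, so the result is deterministic.
#'
#' @param measurements Tibble from [extract_cdr()].
#' @return Tibble with one row per (subject, eye) present in the input.
#' @export
most_recent_cdr <- function(measurements) {
  if (nrow(measurements) == 0) return(as_tibble(measurements))
  keys <- intersect(c("subject_id", "eye"), names(measurements))
  as_tibble(measurements) %>%
    mutate(.ord = row_number()) %>%
    arrange(.data$doc_date, .data$char_offset, .data$.ord) %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    slice(n()) %>%
    ungroup() %>%
    select(-".ord")
}

#' Write CDR extraction results as CSV files
#'
#' Emits `cdr_measurements.csv` (subject, eye, value, axis, date, span) and
#' `cdr_misses.csv` (the extraction report) under `dir`.
#'
#' @param measurements Result of [extract_cdr()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cdr_results <- function(measurements, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(measurements),
                   file.path(dir, "cdr_measurements.csv"), progress = FALSE)
  readr::write_csv(cdr_extraction_report(measurements),
                   file.path(dir, "cdr_misses.csv"), progress = FALSE)
  invisible(dir)
}

## ---- diagnosis statements ---------------------------------------------------

POAG_STATEMENT_RX <- paste0(
  "(?i)(?:primary\\s+open[\\s-]*angle\\s+glaucoma",
  "|(?<![[:alnum:]])poag(?![[:alnum:]]))"
)

DIAGNOSIS_LABELS <- c("POAG", "uveitic", "chronic_angle_closure", "pediatric",
                      "neovascular", "steroid_responder", "ambiguous",
                      "general_glaucoma")

#' Detect written glaucoma diagnosis statements in documents
#'
#' Pattern-matches diagnosis language in the given document types (default:
#' ophthalmology letters and clinic notes).  "primary open-angle glaucoma"
#' or standalone "POAG" yields a `POAG` statement; configured subtype
#' phrases ("neovascular glaucoma", ...) yield their label; ambiguity
#' phrases ("glaucoma suspect", "ocular hypertension", "advanced glaucoma")
#' yield `ambiguous`; a glaucoma spelling variant not contained in any of
#' the above yields `general_glaucoma`.  A document may yield several
#' statements.
#'
#' @param documents Documents tibble or `emr_cohort`.
#' @param lexicon A `poag_lexicon`.
#' @param doc_types Document types to scan.
#' @return Tibble: `document_id`, `subject_id`, `subtype_label`, `phrase`,
#'   `char_offset`, `doc_date`.
#' @examples
#' docs <- tibble::tibble(
#'   document_id = "D1", subject_id = "S1", doc_type = "ophtho_letter",
#'   doc_date = as.Date("2012-05-01"),
#'   text = "Impression: primary open-angle glaucoma, OU."
#' )
#' detect_diagnosis_statements(docs)
#' @export
detect_diagnosis_statements <- function(documents,
                                        lexicon = default_lexicon(),
                                        doc_types = c("ophtho_letter",
                                                      "clinic_note")) {
  if (inherits(documents, "emr_cohort")) documents <- documents$documents
  documents <- filter(documents, .data$doc_type %in% doc_types)
  empty <- tibble(document_id = character(), subject_id = character(),
                  subtype_label = character(), phrase = character(),
                  char_offset = integer(), doc_date = as.Date(character()))
  if (nrow(documents) == 0) return(empty)

  out <- list()
  for (i in seq_len(nrow(documents))) {
    doc <- documents[i, ]
    text <- doc$text
    if (is.na(text) || !nzchar(text)) next
    low <- tolower(text)

    spans <- list()
    add_spans <- function(label, tbl) {
      if (nrow(tbl) > 0) {
        tbl$subtype_label <- label
        spans[[length(spans) + 1]] <<- tbl
      }
    }
    add_spans("POAG", rx_all(POAG_STATEMENT_RX, text))
    for (lab in names(lexicon$other_subtype_labels)) {
      for (ph in lexicon$other_subtype_labels[[lab]]) {
        add_spans(lab, rx_all(ph, low, perl = FALSE))
      }
    }
    for (ph in lexicon$ambiguity_phrases) {
      add_spans("ambiguous", rx_all(ph, low, perl = FALSE))
    }
    qualified <- if (length(spans) > 0) list_rbind(spans) else
      tibble(start = integer(), end = integer(), match = character(),
             subtype_label = character())

    # bare spelling variants not inside any qualified phrase -> general mention
    general <- list()
    for (v in lexicon$glaucoma_spelling_variants) {
      hits <- rx_all(word_bounded(v), low)
      if (nrow(hits) == 0) next
      covered <- map_lgl(seq_len(nrow(hits)), function(h) {
        any(qualified$start <= hits$start[h] & qualified$end >= hits$end[h])
      })
      hits <- hits[!covered, , drop = FALSE]
      if (nrow(hits) > 0) {
        hits$subtype_label <- "general_glaucoma"
        general[[length(general) + 1]] <- hits
      }
    }
    all_spans <- bind_rows(qualified, if (length(general) > 0) list_rbind(general))
    if (nrow(all_spans) == 0) next
    out[[length(out) + 1]] <- tibble(
      document_id = doc$document_id, subject_id = doc$subject_id,
      subtype_label = all_spans$subtype_label,
      phrase = substr(text, all_spans$start, all_spans$end),
      char_offset = all_spans$start, doc_date = doc$doc_date
    )
  }
  if (length(out) == 0) return(empty)
  res <- list_rbind(out)
  res$.doc_ord <- match(res$document_id, documents$document_id)
  res <- arrange(res, .data$.doc_ord, .data$char_offset, .data$subtype_label) %>%
    distinct()
  res$.doc_ord <- NULL
  res
}
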