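# The case/control decision tree.  Per subject, in order:
#   1. eligibility screen: age strictly over the case minimum at the
#      reference date AND at least one ophthalmology or general-clinic CPT;
#   2. case branch: any POAG ICD-9 (365.11) -> adjudicate into
#      definite / potential / indeterminate tiers;
#   3. control branch: no glaucoma-family ICD-9 (365.x), no glaucoma
#      spelling variant in problem lists or clinic notes, and age at or
#      above the control minimum;
#   4. everything else: excluded_from_controls (glaucoma evidence without a
#      POAG code, or too young for the control arm).
# Exactly one status per subject; the case tiers and the control arm are
# disjoint by construction.

PHENOTYPE_STATUSES <- c("ineligible", "case_definite", "case_potential",
                        "case_indeterminate", "control",
                        "excluded_from_controls")

DEFAULT_AS_OF <- as.Date("2013-03-20")

## ---- per-subject evidence summaries ----------------------------------------

# lexical medication match: a configured name contained in the (lowercase)
# mention; no RxNorm/ATC normalization
match_medications <- function(medications, med_list) {
  if (nrow(medications) == 0 || length(med_list) == 0) {
    return(medications[0, ])
  }
  hit <- map_lgl(tolower(medications$drug_name), function(d) {
    any(map_lgl(med_list, ~ grepl(.x, d, fixed = TRUE)))
  })
  medications[hit, , drop = FALSE]
}

subject_evidence <- function(cohort, as_of, lexicon) {
  demo <- cohort$demographics
  ev <- cohort$coded_events
  qualifying_cpt <- union(lexicon$ophtho_cpt, lexicon$general_clinic_cpt)

  cpt_ev <- filter(ev, .data$code_system == "CPT")
  icd_ev <- filter(ev, .data$code_system == "ICD9")

  by_subject <- function(tbl, col = "subject_id") split(tbl, tbl[[col]])

  has <- function(ids) demo$subject_id %in% ids
  poag_dates <- icd_ev %>%
    filter(.data$code == lexicon$poag_icd9) %>%
    group_by(.data$subject_id) %>%
    summarise(n_poag_dates = dplyr::n_distinct(.data$event_date))

  meds <- match_medications(cohort$medications, lexicon$glaucoma_medications)

  surg_docs <- filter(cohort$documents, .data$doc_type == "surgical_report")
  surgery_hits <- find_terms(surg_docs, lexicon$poag_surgery_phrases,
                             whole_word = FALSE)

  text_docs <- filter(cohort$documents,
                      .data$doc_type %in% c("problem_list", "clinic_note"))
  variant_hits <- find_terms(text_docs, lexicon$glaucoma_spelling_variants,
                             whole_word = FALSE)

  tibble(
    subject_id = demo$subject_id,
    age = unname(age_at(demo, as_of)),
    has_qualifying_cpt = has(cpt_ev$subject_id[cpt_ev$code %in% qualifying_cpt]),
    has_fundus_cpt = has(cpt_ev$subject_id[cpt_ev$code %in% lexicon$fundus_cpt]),
    has_glaucoma_icd = has(icd_ev$subject_id[is_glaucoma_icd9(icd_ev$code, lexicon)]),
    n_poag_dates = {
      m <- match(demo$subject_id, poag_dates$subject_id)
      ifelse(is.na(m), 0L, poag_dates$n_poag_dates[m])
    },
    has_glaucoma_med = has(meds$subject_id),
    has_surgery_report = has(surgery_hits$subject_id),
    has_text_variant = has(variant_hits$subject_id)
  )
}

#' Screen subjects for study eligibility
#'
#' A subject is eligible when strictly older than the case minimum age
#' (default 20 years) at the reference date and when the record holds at
#' least one CPT code for ophthalmology or general clinic procedures.
#'
#' @param cohort An `emr_cohort`.
#' @param as_of Reference `Date` for age calculation (default 2013-03-20).
#' @param lexicon A `poag_lexicon`.
#' @return Tibble: `subject_id`, `eligible`, `reasons` (list of reason codes
#'   for ineligible subjects: `AGE_BELOW_MIN`, `NO_QUALIFYING_CPT`).
#' @export
screen_eligibility <- function(cohort, as_of = DEFAULT_AS_OF,
                               lexicon = default_lexicon()) {
  evd <- subject_evidence(cohort, as_of, lexicon)
  tibble(
    subject_id = evd$subject_id,
    eligible = evd$age > lexicon$case_min_age & evd$has_qualifying_cpt,
    reasons = map2(evd$age > lexicon$case_min_age, evd$has_qualifying_cpt,
                   function(a, c) {
                     r <- character()
                     if (!a) r <- c(r, "AGE_BELOW_MIN")
                     if (!c) r <- c(r, "NO_QUALIFYING_CPT")
                     r
                   })
  )
}

#' Flag POAG case candidates
#'
#' A candidate holds at least one ICD-9 code equal to the POAG code
#' (365.11).  Additional glaucoma-subtype codes never disqualify a
#' candidate (mixed-mechanism and progressing glaucomas are real).
#'
#' @inheritParams screen_eligibility
#' @return Tibble: `subject_id`, `candidate`.
#' @export
classify_case_candidate <- function(cohort, lexicon = default_lexicon()) {
  icd <- filter(cohort$coded_events, .data$code_system == "ICD9",
                .data$code == lexicon$poag_icd9)
  tibble(
    subject_id = cohort$demographics$subject_id,
    candidate = cohort$demographics$subject_id %in% icd$subject_id
  )
}

#' Classify subjects into the control arm
#'
#' A control's record is devoid of any glaucoma-family ICD-9 code (365.x),
#' yields zero matches for the seven glaucoma spelling variants in problem
#' lists and clinic notes, and the subject is at or above the control
#' minimum age (default 40; younger subjects are excluded to reduce
#' contamination with future cases).
#'
#' @inheritParams screen_eligibility
#' @return Tibble: `subject_id`, `control`, `reasons` (exclusion reason
#'   codes: `GLAUCOMA_ICD_PRESENT`, `TEXT_GLAUCOMA_MENTION`,
#'   `AGE_BELOW_MIN`).
#' @export
classify_control <- function(cohort, as_of = DEFAULT_AS_OF,
                             lexicon = default_lexicon()) {
  evd <- subject_evidence(cohort, as_of, lexicon)
  tibble(
    subject_id = evd$subject_id,
    control = !evd$has_glaucoma_icd & !evd$has_text_variant &
      evd$age >= lexicon$control_min_age,
    reasons = pmap(list(evd$has_glaucoma_icd, evd$has_text_variant,
                        evd$age >= lexicon$control_min_age),
                   function(icd, txt, age_ok) {
                     r <- character()
                     if (icd) r <- c(r, "GLAUCOMA_ICD_PRESENT")
                     if (txt) r <- c(r, "TEXT_GLAUCOMA_MENTION")
                     if (!age_ok) r <- c(r, "AGE_BELOW_MIN")
                     r
                   })
  )
}

## ---- case adjudication ------------------------------------------------------

# Definite case, either of:
#   (i)  a written POAG diagnosis statement in an ophthalmologist/optometrist
#        letter (ophtho_letter documents);
#   (ii) ALL of: >= 2 POAG ICD-9 mentions on distinct calendar dates, a
#        glaucoma medication mention, and a POAG surgery phrase in a
#        surgical report.
# Potential case, ALL of: >= 1 POAG ICD-9, a fundus/ophthalmology exam CPT,
#   a glaucoma medication, and a POAG/glaucoma text mention in a clinic note
#   or problem list.  Ambiguity phrases ("advanced glaucoma", "ocular
#   hypertension", "glaucoma suspect") and other-subtype phrases never count
#   as qualifying text.
# Otherwise indeterminate, tagged OTHER_SUBTYPE_ONLY / AMBIGUOUS_PHRASE when
# those patterns are the only textual glaucoma evidence.

#' Adjudicate POAG case candidates into definite/potential/indeterminate
#'
#' @inheritParams screen_eligibility
#' @param subjects Subject ids to adjudicate; defaults to all case
#'   candidates per [classify_case_candidate()].
#' @return Tibble: `subject_id`, `status` (`case_definite`,
#'   `case_potential`, `case_indeterminate`), `reasons` (list of reason
#'   codes).
#' @export
adjudicate_case <- function(cohort, lexicon = default_lexicon(),
                            subjects = NULL) {
  if (is.null(subjects)) {
    cand <- classify_case_candidate(cohort, lexicon)
    subjects <- cand$subject_id[cand$candidate]
  }
  if (length(subjects) == 0) {
    return(tibble(subject_id = character(), status = character(),
                  reasons = list()))
  }
  evd <- subject_evidence(cohort, DEFAULT_AS_OF, lexicon)
  evd <- evd[match(subjects, evd$subject_id), ]

  letters <- filter(cohort$documents, .data$doc_type == "ophtho_letter",
                    .data$subject_id %in% subjects)
  letter_stmts <- detect_diagnosis_statements(letters, lexicon,
                                              doc_types = "ophtho_letter")
  note_docs <- filter(cohort$documents,
                      .data$doc_type %in% c("clinic_note", "problem_list"),
                      .data$subject_id %in% subjects)
  note_stmts <- detect_diagnosis_statements(
    note_docs, lexicon, doc_types = c("clinic_note", "problem_list")
  )

  res <- purrr::map(seq_along(subjects), function(i) {
    sid <- subjects[i]
    e <- evd[i, ]
    ls <- filter(letter_stmts, .data$subject_id == sid)
    ns <- filter(note_stmts, .data$subject_id == sid)

    poag_letter <- any(ls$subtype_label == "POAG")
    qualifying_text <- any(ns$subtype_label %in% c("POAG", "general_glaucoma"))
    other_subtype <- any(c(ls$subtype_label, ns$subtype_label) %in%
                           names(lexicon$other_subtype_labels))
    ambiguous <- any(c(ls$subtype_label, ns$subtype_label) == "ambiguous")

    reasons <- c("POAG_ICD_PRESENT")
    if (poag_letter) {
      status <- "case_definite"
      reasons <- c(reasons, "DIAGNOSIS_STATEMENT_POAG")
    } else if (e$n_poag_dates >= 2 && e$has_glaucoma_med &&
                 e$has_surgery_report) {
      status <- "case_definite"
      reasons <- c(reasons, "TWO_INDEPENDENT_POAG_CODES",
                   "GLAUCOMA_MED_PRESENT", "POAG_SURGERY_PRESENT")
    } else if (e$has_fundus_cpt && e$has_glaucoma_med && qualifying_text) {
      status <- "case_potential"
      reasons <- c(reasons, "FUNDUS_CPT_PRESENT", "GLAUCOMA_MED_PRESENT",
                   "TEXT_GLAUCOMA_MENTION")
    } else {
      status <- "case_indeterminate"
      if (other_subtype && !poag_letter && !qualifying_text) {
        reasons <- c(reasons, "OTHER_SUBTYPE_ONLY")
      }
      if (ambiguous && !poag_letter && !qualifying_text) {
        reasons <- c(reasons, "AMBIGUOUS_PHRASE")
      }
    }
    tibble(subject_id = sid, status = status, reasons = list(reasons))
  })
  list_rbind(res)
}

#' Run the full POAG phenotyping decision tree over a cohort
#'
#' Applies the eligibility screen, then the case branch (candidate
#' detection and definite/potential/indeterminate adjudication), then the
#' control branch.  Every subject receives exactly one status; case tiers
#' and controls are disjoint by construction; the run is deterministic
#' given its inputs.
#'
#' @inheritParams screen_eligibility
#' @return A `poag_assignments` tibble: `subject_id`, `status` (factor over
#'   `ineligible`, `case_definite`, `case_potential`, `case_indeterminate`,
#'   `control`, `excluded_from_controls`), `reasons` (list of reason
#'   codes), `as_of`.  A run manifest (reference date, lexicon hash, status
#'   counts) is attached as the `"manifest"` attribute.
#' @examples
#' rec <- cohort_recipe(seed = 1, n_subjects = 20)
#' gen <- generate_cohort(rec)
#' run_phenotyping(gen$cohort)
#' @export
run_phenotyping <- function(cohort, as_of = DEFAULT_AS_OF,
                            lexicon = default_lexicon()) {
  stopifnot(inherits(cohort, "emr_cohort"), inherits(as_of, "Date"))
  if (anyDuplicated(cohort$demographics$subject_id)) {
    abort("duplicate subject_id in cohort")
  }
  n <- nrow(cohort$demographics)
  if (n == 0) {
    out <- tibble(subject_id = character(),
                  status = factor(character(), levels = PHENOTYPE_STATUSES),
                  reasons = list(), as_of = as.Date(character()))
    class(out) <- c("poag_assignments", class(out))
    return(out)
  }

  elig <- screen_eligibility(cohort, as_of, lexicon)
  cand <- classify_case_candidate(cohort, lexicon)
  ctrl <- classify_control(cohort, as_of, lexicon)

  adjudicate_ids <- elig$subject_id[elig$eligible & cand$candidate]
  adj <- adjudicate_case(cohort, lexicon, subjects = adjudicate_ids)

  status <- character(n)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- elig$subject_id[i]
    if (!elig$eligible[i]) {
      status[i] <- "ineligible"
      reasons[[i]] <- elig$reasons[[i]]
    } else if (cand$candidate[i]) {
      j <- match(sid, adj$subject_id)
      status[i] <- adj$status[j]
      reasons[[i]] <- adj$reasons[[j]]
    } else if (ctrl$control[i]) {
      status[i] <- "control"
      reasons[[i]] <- character()
    } else {
      status[i] <- "excluded_from_controls"
      reasons[[i]] <- ctrl$reasons[[i]]
    }
  }

  out <- tibble(
    subject_id = elig$subject_id,
    status = factor(status, levels = PHENOTYPE_STATUSES),
    reasons = reasons,
    as_of = as_of
  )
  counts <- table(out$status)
  attr(out, "manifest") <- list(
    as_of = format(as_of, "%Y-%m-%d"),
    lexicon_hash = rlang::hash(unclass(lexicon)),
    n_subjects = n,
    status_counts = as.list(stats::setNames(as.integer(counts), names(counts)))
  )
  class(out) <- c("poag_assignments", class(out))
  out
}

#' Write phenotype assignments and a run manifest
#'
#' Emits `assignments.csv` (`subject_id`, `status`, semicolon-joined
#' `reasons`) and `manifest.json` (reference date, lexicon hash, status
#' counts) under `dir`.
#'
#' @param assignments Result of [run_phenotyping()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assignments <- function(assignments, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- tibble(
    subject_id = assignments$subject_id,
    status = as.character(assignments$status),
    reasons = map_chr(assignments$reasons, paste, collapse = ";")
  )
  readr::write_csv(flat, file.path(dir, "assignments.csv"), progress = FALSE)
  manifest <- attr(assignments, "manifest")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
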