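# Independent brute-force reference implementations used as oracles.  These
# re-evaluate every criterion from scratch with plain base-R loops and their
# own text handling; they share nothing with the package internals beyond
# the lexicon's configured lists.

oracle_phenotype_one <- function(cohort, sid, as_of, lex) {
  demo <- cohort$demographics[cohort$demographics$subject_id == sid, ]
  ev <- cohort$coded_events[cohort$coded_events$subject_id == sid, ]
  meds <- cohort$medications[cohort$medications$subject_id == sid, ]
  docs <- cohort$documents[cohort$documents$subject_id == sid, ]

  age <- as.integer(format(as_of, "%Y")) - demo$birth_year
  cpts <- ev$code[ev$code_system == "CPT"]
  icds <- ev$code[ev$code_system == "ICD9"]

  if (!(age > lex$case_min_age &&
          any(cpts %in% c(lex$ophtho_cpt, lex$general_clinic_cpt)))) {
    return("ineligible")
  }

  if (any(icds == lex$poag_icd9)) {
    letter_txt <- tolower(docs$text[docs$doc_type == "ophtho_letter"])
    poag_rx <- "primary open[- ]?angle glaucoma|(^|[^a-z0-9])poag($|[^a-z0-9])"
    poag_letter <- any(grepl(poag_rx, letter_txt))
    poag_dates <- unique(ev$event_date[ev$code_system == "ICD9" &
                                         ev$code == lex$poag_icd9])
    has_med <- FALSE
    for (m in lex$glaucoma_medications) {
      if (any(grepl(m, tolower(meds$drug_name), fixed = TRUE))) has_med <- TRUE
    }
    surg_txt <- tolower(docs$text[docs$doc_type == "surgical_report"])
    has_surg <- FALSE
    for (p in lex$poag_surgery_phrases) {
      if (any(grepl(p, surg_txt, fixed = TRUE))) has_surg <- TRUE
    }
    if (poag_letter || (length(poag_dates) >= 2 && has_med && has_surg)) {
      return("case_definite")
    }
    note_txt <- tolower(docs$text[docs$doc_type %in%
                                    c("clinic_note", "problem_list")])
    # qualifying text: POAG mention, or a spelling variant left over after
    # deleting every subtype and ambiguity phrase occurrence
    qual <- any(grepl(poag_rx, note_txt))
    if (!qual) {
      stripped <- note_txt
      for (p in c(unlist(lex$other_subtype_labels), lex$ambiguity_phrases)) {
        stripped <- gsub(p, " ", stripped, fixed = TRUE)
      }
      for (v in lex$glaucoma_spelling_variants) {
        if (any(grepl(v, stripped, fixed = TRUE))) qual <- TRUE
      }
    }
    has_fundus <- any(cpts %in% lex$fundus_cpt)
    if (has_fundus && has_med && qual) return("case_potential")
    return("case_indeterminate")
  }

  glauc_icd <- any(substr(icds, 1, nchar(lex$glaucoma_icd9_prefix)) ==
                     lex$glaucoma_icd9_prefix)
  note_txt <- tolower(docs$text[docs$doc_type %in%
                                  c("clinic_note", "problem_list")])
  txt_hit <- FALSE
  for (v in lex$glaucoma_spelling_variants) {
    if (any(grepl(v, note_txt, fixed = TRUE))) txt_hit <- TRUE
  }
  if (!glauc_icd && !txt_hit && age >= lex$control_min_age) return("control")
  "excluded_from_controls"
}

oracle_phenotype <- function(cohort, as_of, lex) {
  sids <- cohort$demographics$subject_id
  vapply(sids, function(s) oracle_phenotype_one(cohort, s, as_of, lex),
         character(1))
}

# sort-and-pick median: odd count -> middle, even -> mean of the two middles
oracle_median <- function(v) {
  if (length(v) == 0) return(NA_real_)
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# brute-force 2x2 tally by explicit looping
oracle_confusion <- function(predicted, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (s in names(predicted)) {
    p <- predicted[[s]]
    t <- truth[[s]]
    if (p == "positive" && t == "positive") tp <- tp + 1L
    if (p == "positive" && t == "negative") fp <- fp + 1L
    if (p == "negative" && t == "negative") tn <- tn + 1L
    if (p == "negative" && t == "positive") fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}
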