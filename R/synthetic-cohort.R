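# Seeded generator of labeled synthetic EMR cohorts.  Each subject is built
# from an archetype template that plants exactly the evidence (or the trap)
# one branch of the phenotyping algorithm keys on, and the truth table
# records the archetype and intended status, so generator-vs-phenotyper
# agreement is a contract test.  Note text is template-based — no free
# generation — so text-extraction ground truth is exact; the templates
# enumerate the surface-form grammar the CDR extractor supports.
#
# Randomness: one pseudo-random stream per subject, derived from
# (seed, subject index), so a subject's record is invariant under changes to
# the rest of the cohort, including reordering of archetypes.

ARCHETYPES <- c(
  definite_by_letter = "case_definite",
  definite_by_triple_evidence = "case_definite",
  potential = "case_potential",
  other_subtype_confounder = "case_indeterminate",
  ambiguous_suspect = "excluded_from_controls",
  misspelled_text_only = "excluded_from_controls",
  clean_control = "control",
  under_age_control_contaminant = "excluded_from_controls",
  ineligible_no_cpt = "ineligible",
  ineligible_young = "ineligible"
)

CASE_ARCHETYPES <- c("definite_by_letter", "definite_by_triple_evidence",
                     "potential")

#' Default archetype mix for generated cohorts
#'
#' Proportions sum to 1 and lean toward controls, echoing the strong
#' control:case imbalance of a real screening population while still
#' exercising every decision-tree branch.
#' @return Named numeric vector over the ten archetypes.
#' @export
default_archetype_mix <- function() {
  c(definite_by_letter = 0.10,
    definite_by_triple_evidence = 0.08,
    potential = 0.10,
    other_subtype_confounder = 0.08,
    ambiguous_suspect = 0.06,
    misspelled_text_only = 0.05,
    clean_control = 0.38,
    under_age_control_contaminant = 0.05,
    ineligible_no_cpt = 0.05,
    ineligible_young = 0.05)
}

# per-kind (location, scale) for measurement streams; locations are the
# published definite-case medians of the validation cohort
default_covariate_params <- function() {
  list(
    sbp = c(134.5, 14.1), dbp = c(74.5, 8.1), bmi = c(30.1, 6.7),
    total_cholesterol = c(183, 40.6), hdl = c(52.5, 25.0),
    ldl = c(103, 42.9), triglycerides = c(125, 76.3),
    height = c(168, 10), weight = c(85, 15)
  )
}

#' Describe a synthetic cohort to generate
#'
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the recipe.
#' @param n_subjects Number of subjects (> 0).
#' @param mix Named proportions over the archetypes (must sum to 1):
#'   `definite_by_letter`, `definite_by_triple_evidence`, `potential`,
#'   `other_subtype_confounder`, `ambiguous_suspect`,
#'   `misspelled_text_only`, `clean_control`,
#'   `under_age_control_contaminant`, `ineligible_no_cpt`,
#'   `ineligible_young`.
#' @param cdr_median,cdr_sd Location and scale of the per-eye planted
#'   cup-to-disc ratio distribution (values are drawn normal, clipped and
#'   reported on the clinical one-decimal grid).
#' @param cdr_miss_frac Fraction of CDR-bearing case records planted with a
#'   key phrase but no value (default 9/132, the observed missing-measure
#'   rate in chart-reviewed records).
#' @param cdr_docs_per_case CDR-bearing notes planted per case subject.
#' @param hypertension_frac Fraction of subjects given an in-window
#'   antihypertensive mention.
#' @param covariate_params Per-kind `c(location, scale)` list for
#'   measurement streams.
#' @return A `cohort_recipe` list.
#' @export
cohort_recipe <- function(seed = 1L,
                          n_subjects = 200L,
                          mix = default_archetype_mix(),
                          cdr_median = 0.7,
                          cdr_sd = 0.22,
                          cdr_miss_frac = 9 / 132,
                          cdr_docs_per_case = 2L,
                          hypertension_frac = 0.5,
                          covariate_params = default_covariate_params()) {
  if (n_subjects <= 0) abort("n_subjects must be > 0")
  if (!setequal(names(mix), names(ARCHETYPES))) {
    abort(sprintf("mix must be named over the archetypes: %s",
                  paste(names(ARCHETYPES), collapse = ", ")))
  }
  if (abs(sum(mix) - 1) > 1e-8) abort("mix proportions must sum to 1")
  if (cdr_miss_frac < 0 || cdr_miss_frac > 1) {
    abort("cdr_miss_frac must be in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         mix = mix[names(ARCHETYPES)], cdr_median = cdr_median,
         cdr_sd = cdr_sd, cdr_miss_frac = cdr_miss_frac,
         cdr_docs_per_case = as.integer(cdr_docs_per_case),
         hypertension_frac = hypertension_frac,
         covariate_params = covariate_params),
    class = "cohort_recipe"
  )
}

# largest-remainder apportionment: deterministic archetype counts
apportion_mix <- function(mix, n) {
  raw <- mix * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

subject_stream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483629)
}

rand_dates <- function(k, from = as.Date("2005-06-01"),
                       to = as.Date("2013-03-01")) {
  span <- as.integer(to - from)
  sort(from + sample.int(span, k, replace = TRUE))
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

draw_cdr_value <- function(recipe) {
  clip(round(stats::rnorm(1, recipe$cdr_median, recipe$cdr_sd), 1), 0.1, 0.9)
}

#' Plant CDR-bearing notes with exact ground truth
#'
#' Emits clinic notes for one subject using the documented surface-form
#' grammar (all key phrases, OD/OS markers, bare `x/y` pairs, and — when
#' `value_free` — a key phrase with no value, emulating records where the
#' measure was never written down).  The returned truth rows record every
#' planted (eye, value, date).
#'
#' @param subject_id Subject the notes belong to.
#' @param dates Document dates, one note per date.
#' @param recipe A [cohort_recipe()] (supplies the value distribution).
#' @param value_free If `TRUE`, every note carries a key phrase but no
#'   value.
#' @param doc_prefix Prefix for generated document ids.
#' @return List with `documents` (documents tibble rows) and `truth`
#'   (tibble: `subject_id`, `document_id`, `eye`, `value`, `doc_date`;
#'   zero rows when `value_free`).
#' @export
plant_cdr_notes <- function(subject_id, dates, recipe, value_free = FALSE,
                            doc_prefix = paste0(subject_id, "-CDR")) {
  docs <- list()
  truth <- list()
  for (k in seq_along(dates)) {
    doc_id <- sprintf("%s%02d", doc_prefix, k)
    if (value_free) {
      text <- sample(c(
        "Optic discs examined. CDR stable, see prior exam for details.",
        "Exam notable for cup-to-disc ratio not recorded today.",
        "Glaucoma follow-up. C/D deferred; IOP 16 OU."
      ), 1)
    } else {
      v1 <- draw_cdr_value(recipe)
      v2 <- draw_cdr_value(recipe)
      template <- sample.int(5, 1)
      text <- switch(template,
        sprintf("Fundus exam: CDR %.1f OD, %.1f OS. Discs sharp.", v1, v2),
        sprintf("On exam the cup-to-disc ratio of %.1f OD and %.1f OS was noted.",
                v1, v2),
        sprintf("Cup to disk ratio: %.1f/%.1f. Maculae flat.", v1, v2),
        sprintf("C/D %.1f O.D., %.1f O.S.; IOP within normal limits.", v1, v2),
        sprintf("Dilated exam shows vertical cup-to-disk ratio %.1f OD, %.1f OS.",
                v1, v2)
      )
      eyes <- if (template == 3) c("unspecified", "unspecified") else c("OD", "OS")
      truth[[length(truth) + 1]] <- tibble(
        subject_id = subject_id, document_id = doc_id, eye = eyes,
        value = c(v1, v2), doc_date = rep(dates[k], 2)
      )
    }
    docs[[length(docs) + 1]] <- tibble(
      document_id = doc_id, subject_id = subject_id, doc_type = "clinic_note",
      doc_date = dates[k], text = text
    )
  }
  list(
    documents = list_rbind(docs),
    truth = if (length(truth) > 0) list_rbind(truth) else
      tibble(subject_id = character(), document_id = character(),
             eye = character(), value = double(),
             doc_date = as.Date(character()))
  )
}

# measurement stream around an index date, clipped to plausibility bounds
plant_measurements <- function(subject_id, index, recipe) {
  rows <- list()
  for (kind in names(recipe$covariate_params)) {
    p <- recipe$covariate_params[[kind]]
    k <- sample(2:4, 1)
    dates <- index + sample(-600:600, k)
    b <- MEASUREMENT_BOUNDS[[kind]]
    vals <- clip(stats::rnorm(k, p[1], p[2]), b[1], b[2])
    rows[[length(rows) + 1]] <- tibble(
      subject_id = subject_id, kind = kind, value = round(vals, 1),
      measure_date = dates
    )
  }
  list_rbind(rows)
}

#' Generate a labeled synthetic EMR cohort
#'
#' Builds each subject from its archetype template (see
#' [default_archetype_mix()] and the vignette for what each plants), using
#' one pseudo-random stream per subject derived from (seed, index).  The
#' result is byte-identical across runs of the same recipe.
#'
#' @param recipe A [cohort_recipe()].
#' @return List with `cohort` (an [emr_cohort()]), `truth` (tibble:
#'   `subject_id`, `archetype`, `intended_status`, `cdr_od`, `cdr_os` —
#'   the latest planted laterality-marked value per eye), and `cdr_truth`
#'   (every planted CDR: `subject_id`, `document_id`, `eye`, `value`,
#'   `doc_date`).
#' @examples
#' gen <- generate_cohort(cohort_recipe(seed = 7, n_subjects = 40))
#' table(gen$truth$intended_status)
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  n <- recipe$n_subjects
  counts <- apportion_mix(recipe$mix, n)
  archetypes <- rep(names(ARCHETYPES), counts)

  # which case subjects get value-free CDR notes: a deterministic, evenly
  # spread subset of the case subjects, sized by cdr_miss_frac
  case_idx <- which(archetypes %in% CASE_ARCHETYPES)
  n_miss <- round(length(case_idx) * recipe$cdr_miss_frac)
  miss_idx <- if (n_miss > 0) {
    case_idx[unique(round(seq(1, length(case_idx), length.out = n_miss)))]
  } else integer()

  parts <- purrr::map(seq_len(n), function(i) {
    set.seed(subject_stream_seed(recipe$seed, i))
    build_subject(sprintf("S%05d", i), archetypes[i], recipe,
                  cdr_value_free = i %in% miss_idx)
  })

  pick <- function(field, empty) {
    got <- purrr::compact(purrr::map(parts, field))
    if (length(got) == 0) empty else list_rbind(got)
  }
  cohort <- emr_cohort(
    demographics = pick("demographics", empty_demographics()),
    coded_events = pick("coded_events", empty_coded_events()),
    medications = pick("medications", empty_medications()),
    measurements = pick("measurements", empty_measurements()),
    documents = pick("documents", empty_documents())
  )
  cdr_truth <- pick("cdr_truth",
                    tibble(subject_id = character(), document_id = character(),
                           eye = character(), value = double(),
                           doc_date = as.Date(character())))
  latest_eye <- function(sid, eye) {
    rows <- cdr_truth[cdr_truth$subject_id == sid & cdr_truth$eye == eye, ]
    if (nrow(rows) == 0) return(NA_real_)
    rows$value[which.max(rows$doc_date)]
  }
  truth <- tibble(
    subject_id = map_chr(parts, ~ .x$demographics$subject_id),
    archetype = archetypes,
    intended_status = unname(ARCHETYPES[archetypes]),
    cdr_od = map_dbl(map_chr(parts, ~ .x$demographics$subject_id),
                     latest_eye, eye = "OD"),
    cdr_os = map_dbl(map_chr(parts, ~ .x$demographics$subject_id),
                     latest_eye, eye = "OS")
  )
  list(cohort = cohort, truth = truth, cdr_truth = cdr_truth)
}

build_subject <- function(sid, archetype, recipe, cdr_value_free = FALSE) {
  lex <- default_lexicon()
  age <- switch(archetype,
    ineligible_young = sample(5:20, 1),
    under_age_control_contaminant = sample(21:39, 1),
    clean_control = sample(41:80, 1),
    ambiguous_suspect = sample(41:80, 1),
    misspelled_text_only = sample(41:80, 1),
    sample(45:85, 1) # case-tier archetypes and remaining adults
  )
  demographics <- tibble(
    subject_id = sid, birth_year = 2013L - as.integer(age),
    sex = sample(c("female", "male"), 1, prob = c(0.6, 0.4)),
    race_ethnicity = "African American"
  )

  events <- list()
  meds <- list()
  docs <- list()
  cdr_truth <- NULL
  doc_n <- 0L
  next_doc <- function() {
    doc_n <<- doc_n + 1L
    sprintf("%s-D%02d", sid, doc_n)
  }
  add_cpt <- function(codes, dates) {
    events[[length(events) + 1]] <<- tibble(
      subject_id = sid, code_system = "CPT", code = codes,
      event_date = dates, source_document_id = NA_character_
    )
  }
  add_icd <- function(codes, dates) {
    events[[length(events) + 1]] <<- tibble(
      subject_id = sid, code_system = "ICD9", code = codes,
      event_date = dates, source_document_id = NA_character_
    )
  }
  add_doc <- function(type, date, text) {
    docs[[length(docs) + 1]] <<- tibble(
      document_id = next_doc(), subject_id = sid, doc_type = type,
      doc_date = date, text = text
    )
  }
  add_med <- function(name, date) {
    meds[[length(meds) + 1]] <<- tibble(
      subject_id = sid, drug_name = name, mention_date = date
    )
  }
  plant_case_cdr <- function(anchor) {
    dates <- sort(anchor + sample(-500:500, recipe$cdr_docs_per_case))
    planted <- plant_cdr_notes(sid, dates, recipe,
                               value_free = cdr_value_free)
    docs[[length(docs) + 1]] <<- planted$documents
    cdr_truth <<- planted$truth
  }

  visit_dates <- rand_dates(sample(2:4, 1))
  anchor <- visit_dates[length(visit_dates)]

  if (archetype == "definite_by_letter") {
    add_icd(lex$poag_icd9, visit_dates[1])
    add_cpt("92014", anchor)
    add_doc("ophtho_letter", anchor, paste(
      "Thank you for referring this pleasant patient.",
      "Impression: Primary open-angle glaucoma, OU, stable.",
      "Plan: continue current drops; return in 4 months."
    ))
    add_med(sample(lex$glaucoma_medications, 1), anchor)
    plant_case_cdr(anchor)
  } else if (archetype == "definite_by_triple_evidence") {
    two_dates <- visit_dates[1] + c(0L, sample(30:400, 1))
    add_icd(rep(lex$poag_icd9, 2), two_dates)
    add_cpt("92012", anchor)
    add_med(sample(lex$glaucoma_medications, 1), two_dates[2])
    add_doc("surgical_report", anchor, sprintf(
      "Operative note: %s performed on the right eye without complication.",
      sample(lex$poag_surgery_phrases, 1)
    ))
    plant_case_cdr(anchor)
  } else if (archetype == "potential") {
    add_icd(lex$poag_icd9, visit_dates[1])
    add_cpt(sample(lex$fundus_cpt, 1), anchor)
    add_med(sample(lex$glaucoma_medications, 1), anchor)
    add_doc("problem_list", anchor,
            "Problem List:\n1. Glaucoma\n2. Essential hypertension")
    plant_case_cdr(anchor)
  } else if (archetype == "other_subtype_confounder") {
    subtype <- sample(names(lex$other_subtype_labels), 1)
    phrase <- lex$other_subtype_labels[[subtype]][1]
    add_icd(lex$poag_icd9, visit_dates[1])
    add_cpt("92004", anchor)
    add_doc("clinic_note", anchor, sprintf(
      "Assessment: %s, followed by outside ophthalmology.", phrase))
  } else if (archetype == "ambiguous_suspect") {
    add_cpt("92004", anchor)
    add_doc("clinic_note", anchor, sample(c(
      "Patient is a glaucoma suspect. Monitor IOP and repeat fields.",
      "Assessment: ocular hypertension vs early glaucoma suspect; recheck.",
      "Advanced glaucoma was discussed as a remote possibility; suspect only."
    ), 1))
  } else if (archetype == "misspelled_text_only") {
    variant <- sample(setdiff(lex$glaucoma_spelling_variants, "glaucoma"), 1)
    add_cpt(sample(lex$general_clinic_cpt, 1), anchor)
    add_doc("clinic_note", anchor, sprintf(
      "Past history of %s per outside records; no current treatment.", variant))
  } else if (archetype %in% c("clean_control", "under_age_control_contaminant")) {
    add_cpt(sample(lex$general_clinic_cpt, length(visit_dates), replace = TRUE),
            visit_dates)
    add_doc("clinic_note", anchor,
            "Annual physical. No acute complaints. Continue current plan.")
  } else if (archetype == "ineligible_no_cpt") {
    add_icd("401.9", visit_dates[1])
    add_doc("clinic_note", anchor, "Telephone encounter: refill request.")
  } else if (archetype == "ineligible_young") {
    add_cpt(sample(lex$general_clinic_cpt, 1), anchor)
    add_doc("clinic_note", anchor, "Well-child visit. Growth on track.")
  }

  measurements <- plant_measurements(sid, anchor, recipe)
  if (stats::runif(1) < recipe$hypertension_frac) {
    add_med(sample(lex$hypertension_medications, 1),
            anchor + sample(-300:300, 1))
  }

  list(
    demographics = demographics,
    coded_events = if (length(events) > 0) list_rbind(events),
    medications = if (length(meds) > 0) list_rbind(meds),
    measurements = measurements,
    documents = if (length(docs) > 0) list_rbind(docs),
    cdr_truth = cdr_truth
  )
}

#' Write a generated cohort plus its truth labels
#'
#' Writes the cohort directory dialect (see [write_cohort()]) along with
#' `truth_labels.csv` and `cdr_truth.csv`.
#'
#' @param generated Result of [generate_cohort()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_generated_cohort <- function(generated, path) {
  write_cohort(generated$cohort, path)
  readr::write_csv(generated$truth, file.path(path, "truth_labels.csv"),
                   progress = FALSE)
  readr::write_csv(generated$cdr_truth, file.path(path, "cdr_truth.csv"),
                   progress = FALSE)
  invisible(path)
}
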