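# Hand-built single-subject records tracing each branch of the decision tree.

cohort_of <- function(demo, events = NULL, meds = NULL, docs = NULL) {
  emr_cohort(demographics = demo, coded_events = events, medications = meds,
             documents = docs)
}

test_that("eligibility needs age over the minimum and a qualifying CPT", {
  co <- cohort_of(demo_row("S1", 1950L),
                  cpt_row("S1", "92014", "2010-01-01"))
  e <- screen_eligibility(co, AS_OF)
  expect_true(e$eligible)

  co <- cohort_of(demo_row("S1", 1994L), cpt_row("S1", "92014", "2010-01-01"))
  e <- screen_eligibility(co, AS_OF) # age 19
  expect_false(e$eligible)
  expect_equal(e$reasons[[1]], "AGE_BELOW_MIN")

  # age exactly the minimum is not "over" it
  co <- cohort_of(demo_row("S1", 1993L), cpt_row("S1", "92014", "2010-01-01"))
  expect_false(screen_eligibility(co, AS_OF)$eligible)

  co <- cohort_of(demo_row("S1", 1963L),
                  icd_row("S1", "365.11", "2010-01-01"))
  e <- screen_eligibility(co, AS_OF) # no CPT at all
  expect_false(e$eligible)
  expect_equal(e$reasons[[1]], "NO_QUALIFYING_CPT")
})

test_that("case candidacy is one POAG code; other subtypes never disqualify", {
  co <- cohort_of(demo_row("S1"), icd_row("S1", "365.11", "2010-01-01"))
  expect_true(classify_case_candidate(co)$candidate)

  co <- cohort_of(demo_row("S1"), dplyr::bind_rows(
    icd_row("S1", "365.11", "2010-01-01"),
    icd_row("S1", "365.23", "2011-01-01")
  ))
  expect_true(classify_case_candidate(co)$candidate)

  co <- cohort_of(demo_row("S1"), icd_row("S1", "365.9", "2010-01-01"))
  expect_false(classify_case_candidate(co)$candidate)
})

test_that("controls are code-free, text-free and at least the minimum age", {
  base_events <- cpt_row("S1", "99213", "2011-05-01")
  co <- cohort_of(demo_row("S1", 1958L), base_events)
  expect_true(classify_control(co, AS_OF)$control)

  co <- cohort_of(demo_row("S1", 1958L), base_events,
                  docs = note_doc("hx of glucoma per outside records"))
  c <- classify_control(co, AS_OF)
  expect_false(c$control)
  expect_equal(c$reasons[[1]], "TEXT_GLAUCOMA_MENTION")

  co <- cohort_of(demo_row("S1", 1974L), base_events) # age 39
  c <- classify_control(co, AS_OF)
  expect_false(c$control)
  expect_equal(c$reasons[[1]], "AGE_BELOW_MIN")

  # spelling variants in an ophtho letter do not trigger the control text
  # screen (it reads problem lists and clinic notes)
  co <- cohort_of(demo_row("S1", 1958L), base_events,
                  docs = note_doc("glaucoma", type = "ophtho_letter"))
  expect_true(classify_control(co, AS_OF)$control)
})

test_that("definite adjudication accepts a POAG letter or triple evidence", {
  # criterion (i): subtype statement in an ophthalmologist letter
  co <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     cpt_row("S1", "92014", "2010-01-01")),
    docs = note_doc("Impression: primary open-angle glaucoma, OU",
                    type = "ophtho_letter")
  )
  a <- adjudicate_case(co)
  expect_equal(a$status, "case_definite")
  expect_true("DIAGNOSIS_STATEMENT_POAG" %in% a$reasons[[1]])

  # a POAG statement in a plain clinic note is NOT criterion (i)
  co_note <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     cpt_row("S1", "92004", "2010-01-01")),
    docs = note_doc("POAG stable")
  )
  expect_equal(adjudicate_case(co_note)$status, "case_indeterminate")

  # criterion (ii): two distinct-date codes + medication + surgery report
  co <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     icd_row("S1", "365.11", "2011-03-01"),
                     cpt_row("S1", "92014", "2010-01-01")),
    meds = med_row("S1", "latanoprost", "2010-06-01"),
    docs = doc_row("S1", "D1", "surgical_report", "2011-04-01",
                   "selective laser trabeculoplasty performed without complication")
  )
  a <- adjudicate_case(co)
  expect_equal(a$status, "case_definite")
  expect_true(all(c("TWO_INDEPENDENT_POAG_CODES", "GLAUCOMA_MED_PRESENT",
                    "POAG_SURGERY_PRESENT") %in% a$reasons[[1]]))

  # same-day duplicate billing is one mention: not definite via (ii)
  co_same_day <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     icd_row("S1", "365.11", "2010-01-01"),
                     cpt_row("S1", "92014", "2010-01-01")),
    meds = med_row("S1", "latanoprost", "2010-06-01"),
    docs = doc_row("S1", "D1", "surgical_report", "2011-04-01",
                   "selective laser trabeculoplasty performed")
  )
  expect_equal(adjudicate_case(co_same_day)$status, "case_indeterminate")
})

test_that("potential cases need code + fundus CPT + medication + text mention", {
  co <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     cpt_row("S1", "92250", "2010-01-01")),
    meds = med_row("S1", "timolol", "2010-06-01"),
    docs = doc_row("S1", "D1", "problem_list", "2010-01-01",
                   "1. Glaucoma 2. Hypertension")
  )
  a <- adjudicate_case(co)
  expect_equal(a$status, "case_potential")

  # drop any leg of the conjunction and the tier is lost
  no_med <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     cpt_row("S1", "92250", "2010-01-01")),
    docs = doc_row("S1", "D1", "problem_list", "2010-01-01", "1. Glaucoma")
  )
  expect_equal(adjudicate_case(no_med)$status, "case_indeterminate")

  no_fundus <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     cpt_row("S1", "99213", "2010-01-01")),
    meds = med_row("S1", "timolol", "2010-06-01"),
    docs = doc_row("S1", "D1", "problem_list", "2010-01-01", "1. Glaucoma")
  )
  expect_equal(adjudicate_case(no_fundus)$status, "case_indeterminate")
})

test_that("ambiguity phrases and other subtypes never count as case evidence", {
  co <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     cpt_row("S1", "92250", "2010-01-01")),
    meds = med_row("S1", "timolol", "2010-06-01"),
    docs = note_doc("patient is a glaucoma suspect")
  )
  a <- adjudicate_case(co)
  expect_equal(a$status, "case_indeterminate")
  expect_true("AMBIGUOUS_PHRASE" %in% a$reasons[[1]])

  co <- cohort_of(
    demo_row("S1"),
    dplyr::bind_rows(icd_row("S1", "365.11", "2010-01-01"),
                     cpt_row("S1", "92004", "2010-01-01")),
    docs = note_doc("neovascular glaucoma secondary to PDR")
  )
  a <- adjudicate_case(co)
  expect_equal(a$status, "case_indeterminate")
  expect_true("OTHER_SUBTYPE_ONLY" %in% a$reasons[[1]])
})

test_that("run_phenotyping partitions the cohort with disjoint statuses", {
  gen <- generate_cohort(cohort_recipe(seed = 5, n_subjects = 80))
  asn <- run_phenotyping(gen$cohort)

  expect_equal(nrow(asn), 80)
  expect_equal(anyDuplicated(asn$subject_id), 0)
  expect_equal(sum(table(asn$status)), 80)
  # no subject is both a case tier and control: one row each, statuses factor
  expect_true(all(!is.na(asn$status)))

  expect_equal(nrow(run_phenotyping(emr_cohort(demo_row(character(0))))), 0)
})

test_that("a non-POAG glaucoma code bars both arms of the tree", {
  co <- cohort_of(demo_row("S1", 1950L),
                  dplyr::bind_rows(icd_row("S1", "365.23", "2010-01-01"),
                                   cpt_row("S1", "99213", "2010-01-01")))
  asn <- run_phenotyping(co, AS_OF)
  expect_equal(as.character(asn$status), "excluded_from_controls")
  expect_true("GLAUCOMA_ICD_PRESENT" %in% asn$reasons[[1]])
})

test_that("evidence monotonicity: POAG codes never move a subject to control", {
  gen <- generate_cohort(cohort_recipe(seed = 6, n_subjects = 40))
  asn0 <- run_phenotyping(gen$cohort)
  controls <- asn0$subject_id[asn0$status == "control"]
  # add a POAG event to every control; none may remain a control
  extra <- icd_row(controls, "365.11", "2010-06-01")
  co2 <- emr_cohort(
    demographics = gen$cohort$demographics,
    coded_events = dplyr::bind_rows(gen$cohort$coded_events, extra),
    medications = gen$cohort$medications,
    measurements = gen$cohort$measurements,
    documents = gen$cohort$documents
  )
  asn1 <- run_phenotyping(co2)
  expect_false(any(asn1$subject_id %in% controls &
                     asn1$status == "control"))

  # deleting all glaucoma evidence from an excluded subject of control age
  # yields control
  excl <- asn0$subject_id[asn0$status == "excluded_from_controls"]
  ages <- age_at(gen$cohort$demographics, AS_OF)
  excl <- excl[ages[excl] >= 40]
  if (length(excl) > 0) {
    keep_ev <- gen$cohort$coded_events
    keep_ev <- keep_ev[!(keep_ev$subject_id %in% excl &
                           keep_ev$code_system == "ICD9" &
                           startsWith(keep_ev$code, "365.")), ]
    docs <- gen$cohort$documents
    docs$text[docs$subject_id %in% excl] <- "routine visit"
    co3 <- emr_cohort(
      demographics = gen$cohort$demographics, coded_events = keep_ev,
      medications = gen$cohort$medications,
      measurements = gen$cohort$measurements, documents = docs
    )
    asn2 <- run_phenotyping(co3)
    expect_true(all(asn2$status[asn2$subject_id %in% excl] == "control"))
  }
})

test_that("assignments write out with joined reasons and a manifest", {
  gen <- generate_cohort(cohort_recipe(seed = 7, n_subjects = 20))
  asn <- run_phenotyping(gen$cohort)
  dir <- withr::local_tempdir()
  write_assignments(asn, dir)
  flat <- readr::read_csv(file.path(dir, "assignments.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(flat), 20)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_subjects, 20)
  expect_equal(man$as_of, "2013-03-20")
})
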