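make_case_control_cohort <- function() {
  emr_cohort(
    demographics = dplyr::bind_rows(demo_row("C1", 1945L),
                                    demo_row("K1", 1950L, sex = "male")),
    coded_events = dplyr::bind_rows(
      # case K1: two POAG codes; first mention anchors the index
      icd_row("K1", "365.11", "2011-02-03"),
      icd_row("K1", "365.11", "2008-05-01"),
      cpt_row("K1", "92014", "2008-05-01"),
      # control C1: CPT visits; the last anchors the index
      cpt_row("C1", "99213", "2009-01-01"),
      cpt_row("C1", "99214", "2012-12-31")
    ),
    documents = doc_row("K1", "DK", "ophtho_letter", "2008-05-01",
                        "Impression: primary open-angle glaucoma")
  )
}

test_that("index dates anchor on first POAG code for cases, last CPT for controls", {
  co <- make_case_control_cohort()
  asn <- run_phenotyping(co, AS_OF)
  idx <- index_dates(co, asn)
  expect_equal(idx$index_date[idx$subject_id == "K1"], as.Date("2008-05-01"))
  expect_equal(idx$index_kind[idx$subject_id == "K1"], "diagnosis")
  expect_equal(idx$index_date[idx$subject_id == "C1"], as.Date("2012-12-31"))
  expect_equal(idx$index_kind[idx$subject_id == "C1"], "last_clinic_visit")

  # single-CPT control: that date
  co1 <- emr_cohort(demo_row("C2", 1950L),
                    coded_events = cpt_row("C2", "99213", "2010-07-07"))
  asn1 <- run_phenotyping(co1, AS_OF)
  idx1 <- index_dates(co1, asn1)
  expect_equal(idx1$index_date, as.Date("2010-07-07"))
})

test_that("hypertension thresholds are strict and the window is two-sided", {
  lex <- default_lexicon()
  index <- as.Date("2010-01-01")
  sbp_hi <- meas_row("S1", "sbp", 150, index + 100)
  expect_true(is_hypertensive(sbp_hi, empty_meds <- med_row("S1", "x", index)[0, ],
                              index, lex))

  # boundary values do not qualify (strict inequalities)
  at_limits <- dplyr::bind_rows(meas_row("S1", "sbp", 140, index),
                                meas_row("S1", "dbp", 90, index))
  expect_false(is_hypertensive(at_limits, empty_meds, index, lex))

  # an antihypertensive mention inside the window qualifies on its own
  expect_true(is_hypertensive(at_limits[0, ],
                              med_row("S1", "lisinopril", index - 300),
                              index, lex))
  # ... but not outside it
  expect_false(is_hypertensive(at_limits[0, ],
                               med_row("S1", "lisinopril", index - 800),
                               index, lex))

  # monotone in evidence: adding a qualifying measurement never flips TRUE->FALSE
  base <- med_row("S1", "lisinopril", index)
  expect_true(is_hypertensive(sbp_hi, base, index, lex))
})

test_that("window membership is symmetric around the index", {
  lex <- default_lexicon()
  index <- as.Date("2010-01-01")
  for (k in c(0, 1, 365, 730, 731, 1000)) {
    plus <- meas_row("S1", "bmi", 30, index + k)
    minus <- meas_row("S1", "bmi", 30, index - k)
    expect_equal(is.na(windowed_median(plus, "bmi", index, lex)),
                 is.na(windowed_median(minus, "bmi", index, lex)),
                 info = paste("offset", k))
  }
  # day 730 is in, day 731 is out
  expect_false(is.na(windowed_median(meas_row("S1", "bmi", 30, index + 730),
                                     "bmi", index, lex)))
  expect_true(is.na(windowed_median(meas_row("S1", "bmi", 30, index + 731),
                                    "bmi", index, lex)))
})

test_that("windowed_median equals the sort-and-pick oracle for lengths 0..20", {
  lex <- default_lexicon()
  index <- as.Date("2010-01-01")
  set.seed(42)
  for (n in 0:20) {
    vals <- round(stats::runif(n, 60, 200), 1)
    meas <- if (n > 0) {
      meas_row("S1", "sbp", vals, index + sample(-700:700, n, replace = TRUE))
    } else {
      meas_row("S1", "sbp", numeric(0), as.Date(character(0)))
    }
    expect_equal(windowed_median(meas, "sbp", index, lex), oracle_median(vals),
                 info = paste("n =", n))
  }
  # spec'd examples
  m3 <- meas_row("S1", "total_cholesterol", c(160, 183, 200), index)
  expect_equal(windowed_median(m3, "total_cholesterol", index, lex), 183)
  m2 <- meas_row("S1", "hdl", c(100, 110), index)
  expect_equal(windowed_median(m2, "hdl", index, lex), 105)
})

test_that("covariate profiles and the cohort summary have the Table-2 shape", {
  gen <- generate_cohort(cohort_recipe(seed = 21, n_subjects = 60))
  asn <- run_phenotyping(gen$cohort)
  prof <- derive_covariates(gen$cohort, asn)

  expect_true(all(prof$age_at_index >= 0))
  expect_true(all(prof$status %in% c("case_definite", "case_potential",
                                     "case_indeterminate", "control")))
  expect_true(all(prof$index_kind[startsWith(prof$status, "case")] == "diagnosis"))
  expect_true(all(prof$index_kind[prof$status == "control"] == "last_clinic_visit"))

  s <- summarize_cohort(prof)
  expect_true(all(c("n", "median_age", "pct_female", "pct_hypertensive",
                    "bmi_median", "bmi_n") %in% names(s)))
  expect_equal(sum(s$n), nrow(prof))

  # spot-check a tiny summary by hand: 3 subjects aged 60/62/64, 2/4 female
  tiny <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    status = "control", index_date = AS_OF, index_kind = "last_clinic_visit",
    age_at_index = c(60L, 62L, 64L, 62L),
    sex = c("female", "female", "male", "male"),
    hypertensive = c(TRUE, FALSE, FALSE, FALSE),
    bmi = c(30.1, 30.1, 30.1, NA)
  )
  st <- summarize_cohort(tiny)
  expect_equal(st$median_age, 62)
  expect_equal(st$pct_female, 50)
  expect_equal(st$pct_hypertensive, 25)
  expect_equal(st$bmi_median, 30.1)
  expect_equal(st$bmi_n, 3L)
})

test_that("a case without any POAG event is a contract violation", {
  co <- emr_cohort(demo_row("S1", 1950L),
                   coded_events = cpt_row("S1", "99213", "2010-01-01"))
  asn <- run_phenotyping(co, AS_OF)
  # forge an inconsistent assignment: upstream should never produce this
  asn$status[1] <- factor("case_definite", levels = levels(asn$status))
  expect_error(index_dates(co, asn), "without a POAG")
})
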