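test_that("find_terms matches case-insensitively, substring or whole word", {
  lex <- default_lexicon()
  m <- find_terms(note_doc("Dx: Gloucoma suspect"),
                  lex$glaucoma_spelling_variants)
  expect_equal(nrow(m), 1)
  expect_equal(m$term, "gloucoma")

  m <- find_terms(note_doc("ophthalmology consult"), lex$control_review_terms,
                  whole_word = FALSE)
  expect_true("ophth" %in% m$term)

  m <- find_terms(note_doc("visionary plan"), "vision", whole_word = TRUE)
  expect_equal(nrow(m), 0)

  # overlapping terms are each reported ("ophth" contains "opth"? it does not,
  # but "glaucoma suspect" hits both the variant and the phrase search)
  m <- find_terms(note_doc("fundus exam; vision stable"),
                  c("fundus", "vision", "us"))
  expect_setequal(m$term, c("fundus", "vision", "us"))

  expect_equal(nrow(find_terms(note_doc(""), "vision")), 0)
})

test_that("whole-word matches are a subset of substring matches", {
  texts <- c("glaucoma.", "visionary vision", "opth/ophth notes",
             "fundus; fundus", "no terms here")
  lex <- default_lexicon()
  for (tx in texts) {
    sub <- find_terms(note_doc(tx), lex$control_review_terms, whole_word = FALSE)
    ww <- find_terms(note_doc(tx), lex$control_review_terms, whole_word = TRUE)
    key <- function(d) paste(d$term, d$char_offset)
    expect_true(all(key(ww) %in% key(sub)), info = tx)
  }
})

test_that("extract_cdr handles the documented surface-form grammar", {
  # laterality markers after the values
  m <- extract_cdr(note_doc("cup-to-disc ratio of 0.7 OD and 0.8 OS"))
  expect_equal(m$eye, c("OD", "OS"))
  expect_equal(m$value, c(0.7, 0.8))

  # bare pair, no laterality -> unspecified
  m <- extract_cdr(note_doc("CDR: 0.95/0.6"))
  expect_equal(m$eye, c("unspecified", "unspecified"))
  expect_equal(m$value, c(0.95, 0.6))

  # markers before values; periods in markers; C/D phrase
  m <- extract_cdr(note_doc("C/D 0.5 O.D., 0.4 O.S."))
  expect_equal(m$eye, c("OD", "OS"))
  expect_equal(m$value, c(0.5, 0.4))

  # hyphen/space tolerance and axis qualifier
  m <- extract_cdr(note_doc("vertical cup to disk ratio 0.6 OD"))
  expect_equal(m$axis, "vertical")
  expect_equal(m$value, 0.6)

  # leading-dot values
  m <- extract_cdr(note_doc("cdr .7 od, .8 os"))
  expect_equal(m$value, c(0.7, 0.8))
  expect_equal(m$eye, c("OD", "OS"))

  # phrase but no value in window -> extraction report, no measurement
  m <- extract_cdr(note_doc("CDR stable, see prior exam"))
  expect_equal(nrow(m), 0)
  expect_equal(cdr_extraction_report(m)$reason, "no_value_in_window")

  # out-of-range candidate is rejected into the report
  m <- extract_cdr(note_doc("CDR 7 today"))
  expect_equal(nrow(m), 0)
  expect_equal(cdr_extraction_report(m)$reason, "value_out_of_range")

  # overlapping phrases ("cup-to-disc ratio (CDR)") report each value once
  m <- extract_cdr(note_doc("cup-to-disc ratio (CDR) 0.3 OD"))
  expect_equal(nrow(m), 1)
  expect_equal(m$value, 0.3)
})

test_that("extract_cdr values stay in [0,1] and spans are verbatim", {
  gen <- generate_cohort(cohort_recipe(seed = 3, n_subjects = 60))
  m <- extract_cdr(gen$cohort)
  expect_true(all(m$value >= 0 & m$value <= 1))
  docs <- gen$cohort$documents
  for (i in seq_len(nrow(m))) {
    text <- docs$text[docs$document_id == m$document_id[i]]
    expect_true(grepl(m$source_span[i], text, fixed = TRUE))
  }
})

test_that("extraction is deterministic across repeated runs", {
  gen <- generate_cohort(cohort_recipe(seed = 4, n_subjects = 30))
  a <- extract_cdr(gen$cohort)
  b <- extract_cdr(gen$cohort)
  expect_identical(a, b)
})

test_that("most_recent_cdr keeps the per-eye latest with deterministic ties", {
  m1 <- dplyr::bind_rows(
    extract_cdr(note_doc("CDR 0.5 OD", "D1", date = "2010-01-01")),
    extract_cdr(note_doc("CDR 0.7 OD", "D2", date = "2012-06-01"))
  )
  out <- most_recent_cdr(m1)
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 0.7)

  # one-sided input: only OS present
  m2 <- extract_cdr(note_doc("CDR 0.4 OS"))
  out <- most_recent_cdr(m2)
  expect_equal(out$eye, "OS")
  expect_equal(out$value, 0.4)

  # same date, same document: later span wins -- checked against a
  # brute-force max over the (date, offset, order) key
  m3 <- extract_cdr(note_doc("CDR 0.2 OD earlier; CDR 0.9 OD later"))
  expect_equal(nrow(m3), 2)
  out <- most_recent_cdr(m3)
  key <- order(m3$doc_date, m3$char_offset, seq_len(nrow(m3)))
  brute <- m3[key[length(key)], ]
  expect_equal(out$value, brute$value)
  expect_equal(out$value, 0.9)

  expect_equal(nrow(most_recent_cdr(extract_cdr(note_doc("no phrases")))), 0)
})

test_that("diagnosis statements are labeled from the closed subtype set", {
  s <- detect_diagnosis_statements(
    note_doc("Impression: primary open-angle glaucoma, OU", type = "ophtho_letter"))
  expect_equal(s$subtype_label, "POAG")

  s <- detect_diagnosis_statements(note_doc("patient is a glaucoma suspect"))
  expect_equal(s$subtype_label, "ambiguous")

  s <- detect_diagnosis_statements(note_doc("neovascular glaucoma secondary to PDR"))
  expect_equal(s$subtype_label, "neovascular")

  # a bare spelling variant with no qualifier is a general mention
  s <- detect_diagnosis_statements(note_doc("followed for glaucoma"))
  expect_equal(s$subtype_label, "general_glaucoma")

  # standalone POAG abbreviation
  s <- detect_diagnosis_statements(note_doc("POAG, stable"))
  expect_equal(s$subtype_label, "POAG")

  # one document may yield several statements
  s <- detect_diagnosis_statements(
    note_doc("ocular hypertension; also uveitic glaucoma per outside notes"))
  expect_setequal(s$subtype_label, c("ambiguous", "uveitic"))

  # surgical reports and problem lists are outside the default scan set
  s <- detect_diagnosis_statements(
    note_doc("glaucoma", type = "surgical_report"))
  expect_equal(nrow(s), 0)
})
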