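# Hand-built micro-cohorts for unit tests.  All fixtures are constructed in
# code; dates are arbitrary but fixed.

demo_row <- function(sid, birth_year = 1950L, sex = "female") {
  tibble::tibble(subject_id = sid, birth_year = as.integer(birth_year),
                 sex = sex, race_ethnicity = "African American")
}

icd_row <- function(sid, code, date) {
  tibble::tibble(subject_id = sid, code_system = "ICD9", code = code,
                 event_date = as.Date(date),
                 source_document_id = NA_character_)
}

cpt_row <- function(sid, code, date) {
  tibble::tibble(subject_id = sid, code_system = "CPT", code = code,
                 event_date = as.Date(date),
                 source_document_id = NA_character_)
}

med_row <- function(sid, drug, date) {
  tibble::tibble(subject_id = sid, drug_name = drug,
                 mention_date = as.Date(date))
}

meas_row <- function(sid, kind, value, date) {
  tibble::tibble(subject_id = sid, kind = kind, value = value,
                 measure_date = as.Date(date))
}

doc_row <- function(sid, doc_id, type, date, text) {
  tibble::tibble(document_id = doc_id, subject_id = sid, doc_type = type,
                 doc_date = as.Date(date), text = text)
}

# single clinic-note document table, for text-mining tests
note_doc <- function(text, doc_id = "D1", sid = "S1", date = "2012-01-01",
                     type = "clinic_note") {
  doc_row(sid, doc_id, type, date, text)
}

AS_OF <- as.Date("2013-03-20")
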