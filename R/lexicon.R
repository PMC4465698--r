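# The algorithm is parameterized by a lexicon: code sets, term lists and
# thresholds.  Defaults ship in inst/extdata/lexicon-default.yml; a user
# config overrides any key.  The object is a plain list blessed with class
# "poag_lexicon" and validated on construction; R copy semantics make it
# effectively immutable after load.

LEXICON_FIELDS <- c(
  "poag_icd9", "glaucoma_icd9_prefix", "ophtho_cpt", "general_clinic_cpt",
  "fundus_cpt", "glaucoma_spelling_variants", "control_review_terms",
  "glaucoma_medications", "poag_surgery_phrases", "other_subtype_labels",
  "ambiguity_phrases", "hypertension_medications", "case_min_age",
  "control_min_age", "sbp_threshold", "dbp_threshold", "covariate_window_days"
)

#' Load the algorithm lexicon, optionally overridden from a config file
#'
#' Reads the packaged defaults and merges any keys present in `path` (a YAML
#' key-value document) over them.  The merged lexicon is validated: the POAG
#' code must start with the glaucoma code prefix, thresholds must be
#' positive, the spelling-variant list must be non-empty, and all phrase
#' lists must be lowercase.  A violating override is fatal, with the violated
#' rule named.
#'
#' @param path Optional YAML config file with overrides; `NULL` means
#'   defaults only.
#' @return A `poag_lexicon` list.  See the packaged
#'   `lexicon-default.yml` for the full key set; code sets and medication
#'   lists there are documented reconstructions of standard clinical
#'   vocabularies and fully configurable.
#' @examples
#' lex <- load_lexicon()
#' lex$poag_icd9
#' length(lex$glaucoma_spelling_variants) # seven variants
#' @export
load_lexicon <- function(path = NULL) {
  defaults <- yaml::read_yaml(
    system.file("extdata", "lexicon-default.yml", package = "poagphen",
                mustWork = TRUE)
  )
  lex <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("lexicon config not found: %s", path))
    overrides <- yaml::read_yaml(path)
    unknown <- setdiff(names(overrides), LEXICON_FIELDS)
    if (length(unknown) > 0) {
      abort(sprintf("unknown lexicon key(s): %s", paste(unknown, collapse = ", ")))
    }
    lex[names(overrides)] <- overrides
  }
  validate_lexicon(lex)
  structure(lex, class = "poag_lexicon")
}

#' @rdname load_lexicon
#' @export
default_lexicon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_lexicon()
    cache
  }
})

validate_lexicon <- function(lex) {
  missing <- setdiff(LEXICON_FIELDS, names(lex))
  if (length(missing) > 0) {
    abort(sprintf("lexicon is missing key(s): %s", paste(missing, collapse = ", ")))
  }
  if (!startsWith(lex$poag_icd9, lex$glaucoma_icd9_prefix)) {
    abort(sprintf(
      "invariant violated: poag_icd9 ('%s') must start with glaucoma_icd9_prefix ('%s')",
      lex$poag_icd9, lex$glaucoma_icd9_prefix
    ))
  }
  for (k in c("case_min_age", "control_min_age", "sbp_threshold",
              "dbp_threshold", "covariate_window_days")) {
    if (!is.numeric(lex[[k]]) || length(lex[[k]]) != 1 || lex[[k]] <= 0) {
      abort(sprintf("invariant violated: %s must be a positive number", k))
    }
  }
  if (length(lex$glaucoma_spelling_variants) == 0) {
    abort("invariant violated: glaucoma_spelling_variants must be non-empty")
  }
  phrase_fields <- c("glaucoma_spelling_variants", "control_review_terms",
                     "glaucoma_medications", "poag_surgery_phrases",
                     "ambiguity_phrases", "hypertension_medications")
  for (k in phrase_fields) {
    v <- unlist(lex[[k]])
    if (any(v != tolower(v))) {
      abort(sprintf("invariant violated: all entries of %s must be lowercase", k))
    }
  }
  subtype_phrases <- unlist(lex$other_subtype_labels)
  if (any(subtype_phrases != tolower(subtype_phrases))) {
    abort("invariant violated: all entries of other_subtype_labels must be lowercase")
  }
  cpt_fields <- c("ophtho_cpt", "general_clinic_cpt", "fundus_cpt")
  for (k in cpt_fields) {
    v <- as.character(unlist(lex[[k]]))
    if (length(v) > 0 && !all(grepl("^[0-9]{5}$", v))) {
      abort(sprintf("invariant violated: %s must contain five-digit CPT codes", k))
    }
  }
  invisible(TRUE)
}

#' @export
print.poag_lexicon <- function(x, ...) {
  cat("<poag_lexicon>\n")
  cat(sprintf("  POAG ICD-9: %s (glaucoma family prefix '%s')\n",
              x$poag_icd9, x$glaucoma_icd9_prefix))
  cat(sprintf("  CPT sets: ophtho %d, general clinic %d, fundus %d\n",
              length(x$ophtho_cpt), length(x$general_clinic_cpt),
              length(x$fundus_cpt)))
  cat(sprintf("  spelling variants: %s\n",
              paste(x$glaucoma_spelling_variants, collapse = ", ")))
  cat(sprintf("  medications: %d glaucoma, %d antihypertensive\n",
              length(x$glaucoma_medications), length(x$hypertension_medications)))
  cat(sprintf("  ages: case > %d, control >= %d; BP thresholds > %d/%d mm Hg; window +/-%d d\n",
              x$case_min_age, x$control_min_age, x$sbp_threshold,
              x$dbp_threshold, x$covariate_window_days))
  invisible(x)
}

#' Test whether an ICD-9 code is in the glaucoma family
#'
#' Hierarchy matching is by string prefix against the configured glaucoma
#' chapter prefix (default `"365."`), so `"365.11"`, `"365.9"` and
#' `"365.23"` all match while `"366.10"` does not.
#'
#' @param code Character vector of ICD-9 codes.
#' @param lexicon A `poag_lexicon`.
#' @return Logical vector.
#' @examples
#' is_glaucoma_icd9(c("365.11", "366.10", "365.9"))
#' @export
is_glaucoma_icd9 <- function(code, lexicon = default_lexicon()) {
  stopifnot(is.character(code), all(nzchar(code)))
  startsWith(code, lexicon$glaucoma_icd9_prefix)
}
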