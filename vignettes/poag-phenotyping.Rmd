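---
title: "Rule-based POAG phenotyping from de-identified EMRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based POAG phenotyping from de-identified EMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poagphen)
library(dplyr)
```

## The problem

Primary open-angle glaucoma (POAG) is the most common glaucoma subtype and a
leading cause of irreversible vision loss, with markedly higher prevalence in
African Americans.  Genetic studies need large case/control cohorts, and
electronic medical records (EMRs) linked to biobanks are an attractive source
— but ocular phenotypes are unusually hard to extract.  The gold standard
(serial fundus photography) often never reaches the structured EMR: eye
clinics may keep paper or scanned-PDF workflows, so the searchable record
holds only billing codes and free-text letters exchanged between
ophthalmologists and referring clinicians.

`poagphen` implements a rule-based phenotyping algorithm for exactly this
setting.  It classifies each subject of a longitudinal, de-identified EMR
cohort into one of six statuses using ICD-9 diagnosis codes, CPT procedure
codes, medication mentions and free text, then adjudicates algorithm-flagged
cases into the evidence tiers a manual chart review would use.  Everything is
driven by a configurable lexicon, and a seeded synthetic-cohort generator
provides labeled fixtures for every branch of the decision tree.

## The decision tree

For each subject, with ages computed as integer year differences (the
de-identified source supplies birth **year** only) at a reference census date
(default 2013-03-20):

1. **Eligibility.** Age strictly over 20 years, and at least one CPT code for
   an ophthalmology exam (92002, 92004, 92012, 92014, 92250) or a general
   clinic visit (99201–99215).  Everyone else is `ineligible`.
2. **Case branch.** Any ICD-9 365.11 (POAG) makes the subject a case
   candidate.  Additional codes for *other* glaucoma subtypes never
   disqualify: mixed-mechanism disease and progression between subtypes are
   clinically real.
3. **Control branch.** A control's record is devoid of any glaucoma-family
   ICD-9 (the 365.x chapter), yields zero hits for the seven spelling
   variants *glaucoma, glaucome, glocoma, gloucoma, gluacoma, glucoma,
   glycoma* in problem lists and clinic notes, and the subject is at least
   40 years old — the age floor reduces contamination of controls with
   future cases.
4. **Everything else** is `excluded_from_controls`: glaucoma evidence without
   a POAG code (e.g. a 365.23 chronic-angle-closure code, or a misspelled
   text mention), or an otherwise clean record under the control age floor.

### Case adjudication tiers

Candidates are adjudicated the way a chart reviewer would triage them:

* `case_definite`, by either criterion:
  (i) a written POAG diagnosis statement ("primary open-angle glaucoma" or
  standalone "POAG") in an **ophthalmologist/optometrist letter**, or
  (ii) *all* of: at least two 365.11 mentions on **distinct calendar dates**,
  a glaucoma medication mention, and a POAG surgery phrase (argon / selective
  / MicroPulse laser trabeculoplasty, Ex-Press mini glaucoma shunt) in a
  surgical report.
* `case_potential`: *all* of one 365.11 mention, a fundus/ophthalmology exam
  CPT (92012, 92014, 92250), a glaucoma medication, and a POAG/glaucoma text
  mention in a clinic note or problem list.
* `case_indeterminate` otherwise, with reason codes `OTHER_SUBTYPE_ONLY`
  (only uveitic / chronic angle closure / pediatric / neovascular /
  steroid-responder language found) or `AMBIGUOUS_PHRASE` ("advanced
  glaucoma", "ocular hypertension", "glaucoma suspect").  Ambiguity phrases
  and other-subtype phrases **never** count as case-supporting text.

Two operationalizations deserve a note, because the underlying clinical
convention leaves them open:

* "Two independent mentions" is read as two events on distinct calendar
  dates, not distinct documents — same-day duplicate billing is one clinical
  encounter.
* Criterion (i) accepts POAG statements only from `ophtho_letter` documents;
  the synthetic generator tags provenance the same way.  A POAG remark in a
  general clinic note contributes to the *potential* tier instead.
* The surgery criterion matches phrases in surgical reports (a configurable
  CPT surgery list could be added to the lexicon); the exam-CPT requirement
  belongs to the potential tier only, and definite criterion (ii) is applied
  exactly as written.

```{r tree}
gen <- generate_cohort(cohort_recipe(seed = 7, n_subjects = 150))
asn <- run_phenotyping(gen$cohort)
count(asn, status)
```

## The lexicon

Every code set, term list and threshold lives in a YAML lexicon
(`inst/extdata/lexicon-default.yml`), overridable via `load_lexicon(path)`.
The seven spelling variants, the control-review terms (*glaucoma, fundus,
opth, ophth, vision*), the surgery phrases and the ambiguity phrases are the
literal validated lists.  Three defaults are **reconstructions**, because the
verbatim source lists were never published: the full glaucoma ICD-9 set (we
use the whole 365.x chapter, which is what "any glaucoma code" denotes in
ICD-9), the CPT sets (the three cited fundus/exam codes plus standard
ophthalmology exam codes and the E/M office-visit range), and the medication
lists (standard glaucoma drug classes — prostaglandin analogs, topical
beta-blockers, alpha agonists, carbonic anhydrase inhibitors, miotics — and
common antihypertensive classes).  All are configurable; an override that
violates a lexicon invariant (e.g. a POAG code outside the glaucoma prefix)
is fatal with the rule named.

## Free-text mining and the CDR extractor

`find_terms()` is a deterministic, case-insensitive substring or whole-word
search; the control branch and the chart-review support function both use it.

`extract_cdr()` recovers cup-to-disc ratio (CDR) measurements — the ratio of
optic cup to optic disc diameter, a glaucoma severity indicator — from
referral letters and clinic notes.  Key phrases (`CDR`, `C/D`,
`cup-to-disc ratio`, `cup-to-disk`, hyphen/space tolerant) must be followed
within a bounded window (default 40 characters; bounded so values are never
captured across sentences) by one or two values in [0, 1], written `0.x`,
`.x`, or as an `x/y` pair.  Laterality comes from the nearest
`OD`/`O.D.`/"right eye" or `OS`/`O.S.`/"left eye" marker within 12
characters; a bare value pair with exactly one marker of each eye nearby is
assigned positionally; otherwise the eye is `unspecified`.  A second value is
only paired with the first when the intervening text is separators or
laterality filler.

Ophthalmologists interchangeably report horizontal, vertical, or
horizontal-to-vertical quotient CDRs; the original validation resolved that
ambiguity by hand.  The extractor therefore emits an `axis` field
(`horizontal`/`vertical` when such a qualifier adjoins the phrase, else
`unspecified`) and leaves reconciliation to the caller rather than silently
guessing.  Phrase hits with no value in the window and out-of-range
candidates go to an extraction report — mirroring real records where the
phrase appears but the measure was never written down — and
`most_recent_cdr()` keeps the latest measurement per eye, with ties broken by
position within the document and then input order, so results are
deterministic.

```{r cdr}
cdr <- extract_cdr(gen$cohort)
most_recent_cdr(cdr) |> count(eye)
cdr_extraction_report(cdr) |> count(reason)
```

## Covariates

For downstream association studies each case anchors on the date of the
*first* 365.11 mention and each control on the *last* CPT visit.  Subjects
are hypertensive if, within ±730 days of the index, any systolic pressure
exceeds 140 mm Hg (strict), any diastolic exceeds 90 mm Hg (strict), or an
antihypertensive is mentioned; any single qualifying reading counts, with no
same-day aggregation.  `windowed_median()` takes the median of in-window
values per measurement kind (even counts average the two middle values), and
`summarize_cohort()` produces the per-status study-characteristics table
(N, median age at index, % female, % hypertensive, medians of the
per-subject medians with non-missing denominators).

The two-year window is read as a centered ±730-day interval around the
index, and both interval ends are inclusive; all of this is configurable.

## Performance arithmetic

`confusion_counts()` tallies the exhaustive 2×2 table; `ppv()`, `npv()`,
`sensitivity()`, `specificity()` and `accuracy()` are exact ratios that
error (rather than return 0) on an empty denominator.  Published
chart-review percentages in this literature are consistent with
**truncation** at one decimal rather than rounding — e.g. a definite-case
PPV of 138/267 = 51.68% printed as 51.6% — so `format_percent_trunc()` is
the default formatter and plain rounding is available by flag.  One caveat
is documented rather than patched: the potential-inclusive accuracy figure
printed alongside these tallies (83.1%) is not derivable from any natural
combination of the published counts ((205+295)/567 = 88.2%), so the package
reproduces the four derivable percentages and leaves that one out.

```{r metrics}
cc <- as_confusion_counts(tp = 138, fp = 129, tn = 295, fn = 5)
tidy(cc)
format_percent_trunc(ppv(cc))
```

## What the synthetic generator emulates — and what it does not

`generate_cohort()` builds each subject from one of ten archetypes, each
planting exactly the evidence (or the trap) one branch keys on:
`definite_by_letter`, `definite_by_triple_evidence`, `potential`,
`other_subtype_confounder`, `ambiguous_suspect`, `misspelled_text_only`,
`clean_control`, `under_age_control_contaminant`, `ineligible_no_cpt`,
`ineligible_young`.  The truth table records archetype, intended status and
every planted CDR value, so generator-vs-phenotyper agreement is a contract
test, and the CDR extractor can be held to precision = recall = 1 on the
fixture grammar.

Generator defaults are fixed study conditions, not tuning knobs: the
planted per-eye CDR distribution is centered on a median of 0.7 (scale
0.22, values reported on the clinical one-decimal grid); the fraction of
CDR-phrase-positive case records carrying no value defaults to 9/132, the
missing-measure rate observed in chart-reviewed records; measurement
streams use typical case medians (BMI 30.1 kg/m², systolic 134.5 mm Hg,
total cholesterol 183 mg/dL, ...); the default archetype mix leans heavily
toward controls as a screening population does.  Randomness is one stream
per subject derived from (seed, subject index), so a subject's record is
invariant under reordering of the rest of the cohort and the whole output
is byte-identical across runs of the same recipe.

Note text is template-based — the templates enumerate the surface-form
grammar the extractor supports — and deliberately adversarial rather than
realistic.  Passing the contract tests therefore shows the implementation
is faithful to the stated rules on records whose structure matches those
rules; it does *not* show how the algorithm performs on real clinical
language, with its negations, section headers, OCR noise and idiosyncratic
abbreviations.  The published review numbers exist precisely because real
performance (definite-case PPV near 52%, control NPV near 98%) can only be
established by manual review.

## Numerical and degenerate-input choices

* Dates are ISO-8601 calendar dates; all comparisons are closed intervals.
  Rows with unparseable dates are quarantined into a load report at read
  time, never silently dropped.
* Codes are stored verbatim as strings; glaucoma-family membership is a
  string-prefix test performed by the lexicon module, not a normalization
  at load.
* Measurement plausibility bounds warn at load but keep the row.
* The percent formatter adds a 1e-9 guard before flooring so exact decimal
  ratios are not truncated one ulp low in binary floating point.
* Empty cohorts, empty documents, value-free phrase hits and one-sided
  (single-eye) CDR inputs all return empty results rather than erroring.
* Medication matching is lexical containment against the configured lists
  (no RxNorm/ATC normalization), matching how the validated algorithm
  searched de-identified text.

## Problem sizes

The test suite exercises oracle agreement on generated cohorts of 200
subjects (against an independently coded brute-force reference that
re-evaluates every criterion from scratch), generator-contract recovery on
all archetypes at 150–200 subjects, CDR-median convergence at 500 subjects,
and windowed-median equivalence with a sort-and-pick oracle for all lengths
0–20.  These sizes make the whole suite run in about a minute while leaving
every branch of the tree represented many times over.

## Limitations

* The algorithm is deliberately simple pattern matching: no negation
  detection, no section segmentation beyond document type, no
  ICD-10/SNOMED mapping.  It was designed for an EMR where richer
  structure is unavailable, and its portability to other institutions'
  records is untested.
* The reconstructed code/medication defaults may differ from the exact
  validated lists; they are configuration, not ground truth.
* Axis ambiguity in CDR reporting is surfaced, not resolved.
* Controls are defined by absence of evidence; without complete workups
  some controls are undiagnosed cases, which is why the control age floor
  and the free-text exclusion exist.
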