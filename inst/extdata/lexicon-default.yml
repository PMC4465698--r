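# Default lexicon for the POAG phenotyping algorithm.  Every key can be
# overridden from a user config passed to load_lexicon().
#
# The ICD-9/CPT code sets, the medication list and the hypertension-medication
# list are documented RECONSTRUCTIONS of the standard clinical vocabularies
# (the verbatim source lists were not published); the spelling variants,
# review terms, surgery phrases and ambiguity phrases are the literal ones the
# algorithm was validated with.

poag_icd9: "365.11"
glaucoma_icd9_prefix: "365."

ophtho_cpt: ["92002", "92004", "92012", "92014", "92250"]
# evaluation & management office-visit range 99201-99215
general_clinic_cpt: ["99201", "99202", "99203", "99204", "99205",
                     "99211", "99212", "99213", "99214", "99215"]
fundus_cpt: ["92012", "92014", "92250"]

glaucoma_spelling_variants:
  - glaucoma
  - glaucome
  - glocoma
  - gloucoma
  - gluacoma
  - glucoma
  - glycoma

control_review_terms: [glaucoma, fundus, opth, ophth, vision]

# reconstruction: prostaglandin analogs, topical beta-blockers, alpha
# agonists, carbonic anhydrase inhibitors, miotics
glaucoma_medications:
  - latanoprost
  - bimatoprost
  - travoprost
  - tafluprost
  - timolol
  - betaxolol
  - levobunolol
  - brimonidine
  - apraclonidine
  - dorzolamide
  - brinzolamide
  - acetazolamide
  - methazolamide
  - pilocarpine

poag_surgery_phrases:
  - argon laser trabeculoplasty
  - selective laser trabeculoplasty
  - micropulse laser trabeculoplasty
  - ex-press mini glaucoma shunt

other_subtype_labels:
  uveitic: [uveitic glaucoma]
  chronic_angle_closure: [chronic angle closure glaucoma,
                          chronic angle-closure glaucoma]
  pediatric: [pediatric glaucoma, congenital glaucoma]
  neovascular: [neovascular glaucoma]
  steroid_responder: [glaucoma steroid responder, steroid responder,
                      steroid-induced glaucoma]

ambiguity_phrases: [advanced glaucoma, ocular hypertension, glaucoma suspect]

# reconstruction: common antihypertensive classes (ACE inhibitors, ARBs,
# thiazides, beta-blockers, calcium-channel blockers, loop diuretics)
hypertension_medications:
  - lisinopril
  - enalapril
  - ramipril
  - losartan
  - valsartan
  - hydrochlorothiazide
  - chlorthalidone
  - metoprolol
  - atenolol
  - carvedilol
  - amlodipine
  - nifedipine
  - diltiazem
  - furosemide
  - spironolactone
  - clonidine
  - hydralazine

case_min_age: 20
control_min_age: 40
sbp_threshold: 140
dbp_threshold: 90
covariate_window_days: 730
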