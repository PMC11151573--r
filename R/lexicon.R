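# Built-in term lexicon for the six audited diseases.
#
# Each disease has one or more EMR lookup codes, each tied to a canonical
# display term (the string the EMR shows when a clinician picks the code from
# the dropdown), plus a set of free-text variants a clinician might type
# instead: abbreviations (T2DM, DMT2), word-order changes, subtype phrasings.
# The lexicon also carries, per disease, one "decoy" pairing: a term that does
# NOT denote the disease but that practice staff have wrongly mapped to one of
# its codes. These pairings seed the invalid-mapping list of the shipped
# dictionary and the invalid-mapping process of the synthetic generator.
#
# Terms are stored in display case; all matching happens on normalized
# (casefolded, whitespace-collapsed) strings.

lexicon_codes <- function() {
  tibble::tribble(
    ~disease,   ~code,       ~canonical_term,
    "asthma",   "C-AST-01",  "Asthma",
    "asthma",   "C-AST-02",  "Bronchial Asthma",
    "ckd",      "C-CKD-01",  "Chronic Kidney Disease",
    "copd",     "C-CPD-01",  "Chronic Obstructive Pulmonary Disease",
    "dementia", "C-DEM-01",  "Dementia",
    "t1dm",     "C-T1D-01",  "Type 1 Diabetes Mellitus",
    "t2dm",     "C-T2D-01",  "Type 2 Diabetes Mellitus"
  )
}

lexicon_variants <- function() {
  tibble::tribble(
    ~disease,   ~term,
    "asthma",   "Asthmatic",
    "asthma",   "Asthma - mild",
    "asthma",   "Allergic asthma",
    "asthma",   "Asthma (exercise induced)",
    "ckd",      "CKD",
    "ckd",      "CKD stage 3",
    "ckd",      "Chronic renal failure",
    "ckd",      "Chronic renal impairment",
    "ckd",      "CRF",
    "copd",     "COPD",
    "copd",     "COAD",
    "copd",     "Chronic obstructive airways disease",
    "copd",     "COPD - emphysema",
    "dementia", "Alzheimer's disease",
    "dementia", "Alzheimers dementia",
    "dementia", "Vascular dementia",
    "dementia", "Dementia - Alzheimer type",
    "t1dm",     "T1DM",
    "t1dm",     "DM1",
    "t1dm",     "IDDM",
    "t1dm",     "Type 1 diabetes",
    "t1dm",     "Diabetes mellitus type 1",
    "t2dm",     "T2DM",
    "t2dm",     "DMT2",
    "t2dm",     "NIDDM",
    "t2dm",     "Type 2 diabetes",
    "t2dm",     "Diabetes mellitus type 2"
  )
}

# Ambiguous strings a curator would refuse to validate: they may or may not
# mean the patient carries the diagnosis.
lexicon_ambiguous <- function() {
  tibble::tribble(
    ~disease,   ~term,
    "asthma",   "Family history of asthma",
    "ckd",      "Renal disease",
    "copd",     "Smokers cough",
    "dementia", "?dementia",
    "dementia", "Memory loss",
    "t1dm",     "Diabetes",
    "t2dm",     "Diabetes"
  )
}

# One wrongly mapped (code, term) pair per disease. The term denotes a
# different condition altogether; counting it under the code's disease would
# create a false-positive coded diagnosis.
lexicon_invalid_mappings <- function() {
  tibble::tribble(
    ~disease,   ~code,      ~term,
    "asthma",   "C-AST-01", "Bronchiectasis",
    "ckd",      "C-CKD-01", "CHD - coronary heart disease",
    "copd",     "C-CPD-01", "Chronic cough",
    "dementia", "C-DEM-01", "Delirium",
    "t1dm",     "C-T1D-01", "Diabetes insipidus",
    "t2dm",     "C-T2D-01", "Gestational diabetes"
  )
}

# All free-text strings the generator may emit for a disease when an entry is
# left uncoded: the canonical lookup terms plus the variant list.
lexicon_freetext_pool <- function(disease) {
  codes <- lexicon_codes()
  vars <- lexicon_variants()
  c(
    codes$canonical_term[codes$disease == disease],
    vars$term[vars$disease == disease]
  )
}
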