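---
title: "Auditing diagnosis undercount in primary-care EMR extracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing diagnosis undercount in primary-care EMR extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

General-practice clinical software stores a diagnosis either as a coded
entry, picked from the software's lookup list, or as a short free-text
string typed directly into the diagnosis field. Most routine secondary
reporting — quality-improvement programs, population-health statistics —
counts only the coded entries. Whenever clinicians record a meaningful share
of diagnoses as free text, those counts understate disease prevalence.

`emraudit` measures that understatement. For each disease it counts, at the
patient level,

* **A** — active patients with at least one *coded* diagnosis entry for the
  disease (the count routine reporting would produce),
* **B** — active patients with at least one *clinically validated free-text*
  diagnosis term, with or without a code (the count a curated digital
  phenotype produces),

and reports the undercount **C = B − A** and the undercount percentage
`100 · (B − A) / B`. A patient contributes at most once to each of A and B
per disease, however many matching rows they have; the "all diagnosis
types" row is the column-wise sum over diseases, so a patient with two
diseases appears twice there. Diagnosis entries of *any* date are eligible,
including entries recorded years before the reporting window — a chronic
diagnosis does not expire.

## Active patients

Counting is restricted to "active" patients in the sense used by Australian
general-practice reporting: three or more consultations within a two-year
window (default 2021-01-01 to 2022-12-31, both endpoints inclusive, because
the period is named by its endpoint dates). Two choices here were genuinely
open and are fixed as follows:

* *Consultations are encounter rows*, so repeat consultations on the same
  day each count — the definition counts consultations, not days.
* A window of any other span is accepted with a warning, since the
  three-consultation threshold is defined over two years.

## The phenotype dictionary

A phenotype definition per disease has three parts: a **code list** (opaque
code strings; the package implements no code-system semantics, since
extracts span software vendors with different internal codes), a **curated
term list** in which every term carries a status — `validated` (the term
unambiguously means the diagnosis was made) or `excluded_ambiguous` (kept
in the file rather than deleted, so curation decisions stay auditable) —
and an **invalid-mapping list** of (code, term) pairs where practice staff
mapped a term onto a code of a different condition. Every code's canonical
lookup term is stored as a validated term.

Matching is *exact on normalized strings*: casefolded, trimmed, internal
whitespace collapsed. Punctuation is preserved — a hyphen can distinguish
real terms, and curators list variants explicitly. No fuzzy or NLP matching
is attempted; diagnosis-field strings are short and structureless, so
curation, not inference, is the intended route to coverage. Classification
of an entry against a disease yields three flags:

* `excluded_invalid` — the (code, term) pair is a listed invalid mapping,
  attributed to the *code's* disease (the false-positive side);
* `coded_match` — the code is in the disease's code list and the pair is
  not invalid-mapped;
* `text_match` — the normalized term is validated for the disease, *or* the
  entry is a coded match (a legitimate coded entry always displays a
  validated lookup term, so `coded_match ⇒ text_match` holds structurally
  and guarantees A ≤ B).

A patient whose only coded entries for a disease are invalid-mapped is
excluded from that disease's coded count and tallied in
`excluded_invalid_n`; the same entry's *term* still text-matches whatever
disease the term actually denotes. `harvest_candidate_terms()` produces the
curation worksheet (distinct normalized terms matching seed patterns,
ranked by distinct-patient frequency) that a clinical reviewer would fill
in; the package never fills the status column itself.

## Statistics

The difference between the coded proportion `a/N` and the validated
proportion `b/N` (N = active cohort size) is tested with the pooled
two-proportion z statistic,

    z = (b/N − a/N) / sqrt(p̂ (1 − p̂) (2/N)),   p̂ = (a + b) / (2N),

with a two-sided normal p-value, rendered below 0.001 as "< 0.001". Two
caveats are deliberate. First, the two groups share patients (every coded
patient is also a validated patient), so treating them as independent
samples is anti-conservative; the package implements the convention used in
published practice-level audits and documents rather than replaces it — a
paired (McNemar-type) test would be the stricter alternative. Second, z² is
algebraically the Pearson chi-square of the 2×2 table `[[a, N−a], [b,
N−b]]`, which the test suite exploits as an independent oracle
(`chisq.test(correct = FALSE)`, tolerance 1e-9).

All statistics are computed unrounded; rounding (two decimals for
percentages and z, three for p) happens only at rendering. Undefined
quantities (undercount with B = 0, z with pooled proportion 0 or 1) are
`NA`, never 0, and are excluded from distribution summaries with their
count reported.

Between-practice variation is summarised as a Tukey boxplot: quartiles by
linear interpolation (`quantile(type = 7)` — boxplot conventions differ, so
the rule is fixed and stated), whiskers at the most extreme values within
1.5·IQR of the quartiles, everything beyond listed as an outlier with its
practice id.

## The synthetic generator

Real audit extracts are governed data and cannot ship with a package, so
`generate_cohort()` produces cohorts with the statistical structure the
audit assumes, plus row-level ground truth, and every pipeline claim is
tested against that ground truth. The generator emulates:

* several practices with a fixed number of enrolled patients each;
* per-patient consultation counts `Poisson(consult_rate)` with dates
  uniform in the window, so only a fraction of patients meet the
  three-consultation rule (default `consult_rate = 6` per two years gives
  roughly 94% active — chronic-disease patients consult often;
  `active_fraction_target` solves the rate for a requested fraction);
* independent per-patient disease indicators at configurable prevalences —
  defaults are the per-disease validated proportions of the published
  84-practice audit whose counts ship with the package;
* **coding propensity** drawn once per practice per disease from a Beta
  distribution, then applied per entry (Bernoulli). This two-level scheme
  reproduces wide between-practice variation in coding without modelling
  clinician behaviour; the Beta form is a modelling choice, not an
  empirical claim. Defaults: Beta with mean equal to the published coded
  fraction per disease and concentration 10. A single probability may be
  given instead (point mass), which the recovery tests use;
* free-text realism: an uncoded entry carries the canonical term, a listed
  abbreviation/word-order variant (probability `variant_rate`, default 0.3),
  and/or a single random character edit (substitute/delete/transpose/insert,
  probability `misspell_rate`, default 0.02). Typos are deliberately *not*
  in the validated list — real audits miss unanticipated spellings, so
  measured undercounts should err conservative. Edits insert or substitute
  letters only, so an edit can never turn one validated term into another
  (e.g. "type 1 diabetes" → "type 2 diabetes" would need a digit);
* **invalid mappings**: per disease, decoy patients (who do not have the
  disease) receive an entry pairing the disease's code with a term denoting
  a different condition, at a rate making the expected invalid share of
  coded entries equal `invalid_mapping_rate` (defaults are the published
  exclusion rates, e.g. 2.58% for dementia);
* historical records: each diagnosis entry is dated before the window
  (uniform over the preceding ten years) with probability
  `historical_fraction` (default 0.3).

One seeded RNG drives all sampling; a fixed config is byte-identical across
runs, and the seed is echoed in the cohort metadata.

What the generator does **not** emulate: clinical narratives, medications,
demographic structure beyond practice membership, patients attending
several practices, coded entries with corrupted display terms, and
diagnosis-field semantics differences between problem-list and
per-encounter recording (the format accepts both; the generator emits one
entry per patient-disease). Passing tests therefore demonstrate that the
*pipeline measures what the generator encodes*, not that real extracts
match the generator.

## Expected undercount and parameter recovery

With mean coding propensity `p` and uncoded-term match probability
`m = 1 − misspell_rate`, a diseased patient is counted in A with
probability `p` and in B with probability `p + (1 − p)·m`, so
`expected_undercount()` returns

    100 · (1 − p) · m / (p + (1 − p) · m).

Decoy (invalid-mapped) patients enter neither A nor B for the audited
disease, so no further adjustment is needed. The acceptance suite runs the
full pipeline on 20 seeded cohorts of 10 practices × 2,200 patients
(≈ 20,600 active each) with *point-mass* propensities at the default
per-disease means, pools A and B per disease across seeds, and requires the
measured undercount to fall within 3 binomial standard errors of the
analytic expectation. Point masses are used because with Beta heterogeneity
the practice-level draw adds variance far exceeding the binomial term at 10
practices; the recovery test is meant to isolate the counting machinery,
while the Beta model itself is checked separately against a direct
Monte-Carlo oracle of the per-practice median. These problem sizes keep the
whole suite and the acceptance script each under a minute or two of compute
while leaving the rarest disease (dementia, prevalence ≈ 0.55%) with over a
hundred validated patients per cohort.

## Degenerate inputs and tie-breaks

Empty diagnosis tables, empty active sets (reported with N = 0 and an
`empty_cohort` flag) and diseases with B = 0 are all legal and produce
defined output. Duplicate diagnosis rows are legal input and never change a
count. Row order never matters: classification is per-entry, counting is
set-based, and the writer sorts nothing it did not sort on generation. A
misspelling edit that would be a no-op (transposing equal adjacent
characters, single-character deletion leaving an empty string) falls back
to substitution.

## Limitations

The pooled z treats overlapping groups as independent (see above). Exact
matching means coverage is only as good as the curated term list — by
design. The generator's Beta propensity and Poisson consultation models are
conveniences, not estimates fitted to any real extract; only their means
are anchored to published counts. Cross-practice patient linkage is out of
scope, so per-practice rows attribute a patient to the practice of each
diagnosis entry.
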