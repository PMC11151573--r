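test_that("normalize_term casefolds, trims and collapses whitespace, idempotently", {
  expect_equal(normalize_term("  Type 2   Diabetes "), "type 2 diabetes")
  expect_equal(normalize_term("DMT2"), "dmt2")
  # punctuation is preserved
  expect_equal(normalize_term("COPD - emphysema"), "copd - emphysema")
  set.seed(42)
  raw <- replicate(50, paste(sample(c(LETTERS, letters, " ", "  ", "-", "/", "?", "2"),
                                    sample(1:12, 1), replace = TRUE), collapse = ""))
  expect_equal(normalize_term(normalize_term(raw)), normalize_term(raw))
})

test_that("the shipped starter dictionary loads with six diseases", {
  path <- system.file("extdata", "phenotype_dictionary.csv", package = "emraudit")
  dict <- load_dictionary(path)
  expect_setequal(unique(dict$codes$disease), audit_diseases())
  expect_true(all(audit_diseases() %in% dict$terms$disease))
  # and it matches the in-code lexicon the generator draws from
  ref <- default_dictionary()
  expect_equal(dplyr::arrange(dict$codes, code), dplyr::arrange(ref$codes, code))
  expect_equal(dplyr::arrange(dict$terms, disease, term),
               dplyr::arrange(ref$terms, disease, term))
  expect_equal(dplyr::arrange(dict$invalid_mappings, code),
               dplyr::arrange(ref$invalid_mappings, code))
})

test_that("conflicting term status and code-without-canonical-term are fatal", {
  conflicted <- write_dict_csv(dplyr::bind_rows(
    dict_row("copd", "code", code = "K9", term = "copd"),
    dict_row("copd", "term", term = "copd", status = "excluded_ambiguous")
  ))
  expect_error(load_dictionary(conflicted), "copd")
  no_canon <- write_dict_csv(dict_row("copd", "code", code = "K9", term = ""))
  expect_error(load_dictionary(no_canon), "canonical")
  bad_pair <- write_dict_csv(dplyr::bind_rows(
    dict_row("copd", "code", code = "K9", term = "copd"),
    dict_row("copd", "invalid_mapping", code = "NOPE", term = "cold")
  ))
  expect_error(load_dictionary(bad_pair), "NOPE")
})

test_that("classification follows the code/term/invalid-mapping rules", {
  dict <- default_dictionary()
  # coded entry with its canonical lookup term: both flags
  r <- classify_entry(list(code = "C-T2D-01", term = "Type 2 Diabetes Mellitus"), dict)
  expect_equal(r$disease, "t2dm")
  expect_true(r$coded_match && r$text_match && !r$excluded_invalid)
  # uncoded validated variant: text match only
  r <- classify_entry(list(code = "", term = "dmt2"), dict)
  expect_equal(r$disease, "t2dm")
  expect_true(!r$coded_match && r$text_match)
  # excluded-ambiguous terms match nothing
  r <- classify_entry(list(code = "", term = "Diabetes"), dict)
  expect_equal(nrow(r), 0)
  # a known invalid (code, term) pair: excluded for the code's disease,
  # never a coded match
  r <- classify_entry(list(code = "C-CKD-01", term = "CHD - coronary heart disease"),
                      dict)
  expect_equal(r$disease, "ckd")
  expect_true(r$excluded_invalid && !r$coded_match && !r$text_match)
})

test_that("an invalid pair whose term is validated elsewhere still text-matches there", {
  dict <- toy_dict()
  r <- classify_entry(list(code = "K1", term = "term y"), dict)
  r <- dplyr::arrange(r, disease)
  expect_equal(r$disease, c("x", "y"))
  expect_true(r$excluded_invalid[r$disease == "x"])
  expect_false(r$coded_match[r$disease == "x"])
  expect_true(r$text_match[r$disease == "y"])
})

test_that("coded_match implies text_match over an exhaustive small enumeration", {
  dict <- toy_dict()
  combos <- tidyr::crossing(
    code = c("", "K1", "K2"),
    term = c("term x", "x variant", "term y", "unrelated thing")
  )
  res <- classify_entries(combos, dict)
  expect_true(all(!res$coded_match | res$text_match))
  expect_true(all(!res$excluded_invalid | !res$coded_match))
  # classification is per-entry: classifying the list equals mapping entry-wise
  one_by_one <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    r <- classify_entry(as.list(combos[i, ]), dict)
    r$entry <- i
    r
  }))
  expect_equal(dplyr::arrange(one_by_one, entry, disease),
               dplyr::arrange(res, entry, disease))
})

test_that("harvest returns patient frequencies for matching terms, ranked", {
  x <- make_extract(tibble::tibble(
    patient_id = c("P1", "P2", "P2", "P3"),
    term = c("Asthma", "asthma - mild", "asthma - mild", "T2DM")
  ))
  w <- harvest_candidate_terms(x, list(asthma = "asthma"))
  expect_equal(nrow(w), 2)
  expect_setequal(w$term, c("asthma", "asthma - mild"))
  # patient frequency, not row frequency: P2's duplicate rows count once
  expect_equal(w$n_patients[w$term == "asthma - mild"], 1L)
  expect_true(all(w$status == ""))
  expect_error(harvest_candidate_terms(x, list()), "pattern")
})

test_that("harvest on an empty extract yields an empty worksheet", {
  x <- make_extract(
    tibble::tibble(patient_id = character(), term = character()),
    patients = tibble::tibble(patient_id = "P1", practice_id = "PR001",
                              birth_year = NA_integer_)
  )
  expect_equal(nrow(harvest_candidate_terms(x, list(asthma = "asthma"))), 0)
})

test_that("harvesting 'diabetes' from generator output surfaces both diabetes types", {
  coh <- generate_cohort(synth_config(seed = 21, n_practices = 4,
                                      patients_per_practice = 400,
                                      misspell_rate = 0))
  w <- harvest_candidate_terms(coh$extract, list(diabetes = "diabetes"))
  expect_true("type 1 diabetes mellitus" %in% w$term)
  expect_true("type 2 diabetes mellitus" %in% w$term)
  expect_true(all(diff(w$n_patients) <= 0))
})
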