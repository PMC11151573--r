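test_that("invalid probabilities are rejected before any sampling", {
  expect_error(synth_config(seed = 1, variant_rate = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(seed = 1,
                            disease_prevalences = stats::setNames(rep(-0.1, 6),
                                                                  audit_diseases())),
               "\\[0, 1\\]")
  expect_error(synth_config(), "seed")
})

test_that("the same seed generates byte-identical cohorts", {
  cfg <- synth_config(seed = 123, n_practices = 3, patients_per_practice = 150)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$extract$patients, b$extract$patients)
  expect_identical(a$extract$encounters, b$extract$encounters)
  expect_identical(a$extract$diagnoses, b$extract$diagnoses)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(synth_config(seed = 124, n_practices = 3,
                                     patients_per_practice = 150))
  expect_false(identical(a$extract$diagnoses, c2$extract$diagnoses))
})

test_that("generated extracts satisfy every model invariant", {
  coh <- generate_cohort(synth_config(seed = 42, n_practices = 4,
                                      patients_per_practice = 200))
  expect_equal(nrow(validate_extract(coh$extract)), 0)
  # ground-truth entry labels align row-for-row with the diagnosis table
  expect_equal(nrow(coh$truth$entries), nrow(coh$extract$diagnoses))
  expect_identical(coh$truth$entries$patient_id, coh$extract$diagnoses$patient_id)
  has_code <- nzchar(coh$extract$diagnoses$code)
  expect_identical(coh$truth$entries$coded, has_code)
})

test_that("full coding with no mapping errors forces zero undercount", {
  ones <- lapply(stats::setNames(audit_diseases(), audit_diseases()), function(d) 1)
  zeros <- stats::setNames(rep(0, 6), audit_diseases())
  cfg <- synth_config(seed = 9, n_practices = 3, patients_per_practice = 300,
                      coding_propensity = ones, invalid_mapping_rate = zeros)
  coh <- generate_cohort(cfg)
  s <- summarise_cohort(coh$extract, active_patients(coh$extract),
                        default_dictionary())
  expect_true(all(s$counts$C == 0))
  expect_true(all(s$counts$excluded_invalid_n == 0))
  stats_tab <- undercount_stats(s$counts, s$N)
  expect_true(all(stats_tab$percent_undercount[stats_tab$B > 0] == 0))
})

test_that("validated counts follow the binomial sampling scheme", {
  # T2DM at the published prevalence, 20,000 patients, near-universal
  # activity, no misspellings: the validated patient count must sit within
  # 3 binomial standard errors of n_active * p.
  p <- 23877 / 456125
  cfg <- synth_config(seed = 77, n_practices = 10, patients_per_practice = 2000,
                      consult_rate = 12, misspell_rate = 0)
  coh <- generate_cohort(cfg)
  act <- active_patients(coh$extract)
  row <- count_disease(coh$extract, act, default_dictionary(), "t2dm")
  expected <- length(act) * p
  expect_lt(abs(row$B - expected), 3 * sqrt(length(act) * p * (1 - p)))
})

test_that("with no misspellings, B equals the ground-truth diseased active set", {
  coh <- generate_cohort(synth_config(seed = 14, n_practices = 4,
                                      patients_per_practice = 300,
                                      misspell_rate = 0))
  act <- active_patients(coh$extract)
  s <- summarise_cohort(coh$extract, act, default_dictionary())
  truth_counts <- coh$truth$patients |>
    dplyr::filter(patient_id %in% act) |>
    dplyr::count(disease)
  for (d in truth_counts$disease) {
    expect_equal(s$counts$B[s$counts$disease == d],
                 truth_counts$n[truth_counts$disease == d],
                 info = d)
  }
})

test_that("corrupt_term honours the configured variant and misspelling rates", {
  quiet <- synth_config(seed = 1, variant_rate = 0, misspell_rate = 0)
  expect_equal(corrupt_term("Type 2 Diabetes Mellitus", "t2dm", quiet),
               "Type 2 Diabetes Mellitus")
  expect_error(corrupt_term("Type 2 Diabetes Mellitus", "gout", quiet), "unknown disease")
  expect_error(corrupt_term("not a term", "t2dm", quiet), "canonical")

  vary <- synth_config(seed = 1, variant_rate = 1, misspell_rate = 0)
  withr::with_seed(31, {
    draws <- replicate(200, corrupt_term("Type 2 Diabetes Mellitus", "t2dm", vary))
  })
  pool <- lexicon <- emraudit:::lexicon_variants()
  pool <- pool$term[pool$disease == "t2dm"]
  expect_true(all(draws %in% pool))
  expect_true(all(c("T2DM", "DMT2") %in% draws))
})

test_that("misspellings are single edits under an independent distance oracle", {
  withr::with_seed(63, {
    sources <- sample(c("asthma", "t2dm", "dmt2", "chronic kidney disease",
                        "copd - emphysema", "dm1"), 200, replace = TRUE)
    for (src in sources) {
      out <- emraudit:::misspell_once(src)
      expect_equal(osa_dist(tolower(src), out), 1, info = paste(src, "->", out))
    }
  })
})

test_that("expected undercount has its closed forms", {
  point8 <- lapply(stats::setNames(audit_diseases(), audit_diseases()), function(d) 0.8)
  cfg <- synth_config(seed = 1, coding_propensity = point8, misspell_rate = 0)
  expect_equal(expected_undercount(cfg, "asthma"), 20)
  point1 <- lapply(stats::setNames(audit_diseases(), audit_diseases()), function(d) 1)
  expect_equal(expected_undercount(synth_config(seed = 1, coding_propensity = point1),
                                   "ckd"), 0)
  beta82 <- lapply(stats::setNames(audit_diseases(), audit_diseases()),
                   function(d) c(8, 2))
  cfg2 <- synth_config(seed = 1, coding_propensity = beta82, misspell_rate = 0)
  expect_equal(expected_undercount(cfg2, "t2dm"), 20)
  expect_error(expected_undercount(cfg2, "gout"), "unknown disease")
})

test_that("the invalid-mapping fraction among coded entries converges to its rate", {
  r <- 0.05
  cfg <- synth_config(seed = 101, n_practices = 10, patients_per_practice = 1500,
                      invalid_mapping_rate = stats::setNames(rep(r, 6),
                                                             audit_diseases()))
  coh <- generate_cohort(cfg)
  ent <- coh$truth$entries[coh$truth$entries$coded, ]
  n <- nrow(ent)
  frac <- mean(ent$is_invalid_mapping)
  expect_lt(abs(frac - r), 3 * sqrt(r * (1 - r) / n))
})

test_that("the active fraction rises with the consultation rate", {
  frac <- vapply(c(2, 4, 8), function(rate) {
    coh <- generate_cohort(synth_config(seed = 55, n_practices = 2,
                                        patients_per_practice = 400,
                                        consult_rate = rate))
    length(active_patients(coh$extract)) / nrow(coh$extract$patients)
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
  # and a requested target fraction is honoured in expectation
  cfg <- synth_config(seed = 56, active_fraction_target = 0.9)
  expect_equal(stats::ppois(2, cfg$consult_rate, lower.tail = FALSE), 0.9,
               tolerance = 1e-6)
})

test_that("historical diagnoses appear at the configured fraction, before the window", {
  cfg <- synth_config(seed = 70, n_practices = 5, patients_per_practice = 1000,
                      historical_fraction = 0.4)
  coh <- generate_cohort(cfg)
  d <- coh$extract$diagnoses$date
  win <- active_window()
  hist_frac <- mean(d < win$start)
  expect_true(all(d[d < win$start] >= win$start - 3652))
  expect_lt(abs(hist_frac - 0.4), 3 * sqrt(0.4 * 0.6 / length(d)))
})
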