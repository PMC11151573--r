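#' Configure a synthetic general-practice cohort
#'
#' Parameterises the synthetic EMR generator. The generator emulates the
#' structure the audit assumes in real extracts: several practices, patients
#' consulting at different rates (so only a fraction meet the three
#' -consultation activity rule), six chronic diseases at fixed prevalences,
#' per-practice heterogeneity in the propensity to code a diagnosis,
#' free-text abbreviation variants and occasional misspellings, a small rate
#' of wrongly code-mapped entries, and diagnosis dates that may precede the
#' active window.
#'
#' Defaults are anchored to the published audit of 84 Australian practices
#' (456,125 active patients) whose per-disease counts ship with the package:
#' disease prevalences are the validated-count proportions and coding
#' -propensity means are the coded fractions observed there (see
#' [published_audit_counts()]); invalid-mapping rates are the exclusion rates
#' it reported.
#'
#' @param seed Integer seed; the same config generates byte-identical output.
#' @param n_practices Number of practices.
#' @param patients_per_practice Patients enrolled per practice.
#' @param window An [active_window()].
#' @param consult_rate Mean consultations per patient over the window
#'   (Poisson).
#' @param active_fraction_target Optional; when supplied, `consult_rate` is
#'   solved so that the expected fraction of patients with >= 3 in-window
#'   consultations equals this value.
#' @param disease_prevalences Named probabilities (per disease) that a patient
#'   truly carries the disease.
#' @param coding_propensity Named list; per disease either a single
#'   probability (every practice codes at that rate) or two Beta shape
#'   parameters from which each practice's coding propensity is drawn once
#'   and then applied per entry.
#' @param variant_rate Probability an uncoded entry uses a listed free-text
#'   variant instead of the canonical term.
#' @param misspell_rate Probability an uncoded term receives a single random
#'   character edit (such typos are not in the validated term list, so they
#'   go unmatched — mirroring real missed spellings).
#' @param invalid_mapping_rate Named probabilities; per disease, the fraction
#'   of coded entries for that disease that are wrong mappings (a term of a
#'   different condition attached to the disease's code).
#' @param historical_fraction Probability a diagnosis entry is dated in the
#'   ten years before the window rather than inside it.
#' @return A validated `synth_config` object.
#' @seealso [generate_cohort()], [expected_undercount()]
#' @export
synth_config <- function(seed,
                         n_practices = 10,
                         patients_per_practice = 500,
                         window = active_window(),
                         consult_rate = 6,
                         active_fraction_target = NULL,
                         disease_prevalences = default_prevalences(),
                         coding_propensity = default_coding_propensity(),
                         variant_rate = 0.3,
                         misspell_rate = 0.02,
                         invalid_mapping_rate = default_invalid_mapping_rates(),
                         historical_fraction = 0.3) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  seed <- as.integer(seed)
  stopifnot(n_practices >= 1, patients_per_practice >= 1)
  check_probs <- function(x, what) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop(sprintf("%s must be probabilities in [0, 1]", what), call. = FALSE)
    }
  }
  check_named <- function(x, what) {
    if (!all(DISEASES %in% names(x))) {
      stop(sprintf("%s must be named for every disease: %s", what,
                   paste(DISEASES, collapse = ", ")), call. = FALSE)
    }
    x[DISEASES]
  }
  disease_prevalences <- check_named(unlist(disease_prevalences), "disease_prevalences")
  check_probs(disease_prevalences, "disease_prevalences")
  invalid_mapping_rate <- check_named(unlist(invalid_mapping_rate), "invalid_mapping_rate")
  check_probs(invalid_mapping_rate, "invalid_mapping_rate")
  coding_propensity <- check_named(coding_propensity, "coding_propensity")
  for (d in DISEASES) {
    spec <- coding_propensity[[d]]
    if (!is.numeric(spec) || !(length(spec) %in% c(1, 2)) || any(spec < 0)) {
      stop("coding_propensity entries must be one probability or two Beta shapes",
           call. = FALSE)
    }
    if (length(spec) == 1) check_probs(spec, "coding_propensity")
  }
  check_probs(c(variant_rate, misspell_rate, historical_fraction),
              "variant/misspell/historical rates")
  if (!is.null(active_fraction_target)) {
    check_probs(active_fraction_target, "active_fraction_target")
    consult_rate <- uniroot(
      function(l) stats::ppois(2, l, lower.tail = FALSE) - active_fraction_target,
      interval = c(1e-9, 1e3)
    )$root
  }
  stopifnot(consult_rate > 0)
  structure(
    list(seed = seed, n_practices = as.integer(n_practices),
         patients_per_practice = as.integer(patients_per_practice),
         window = window, consult_rate = consult_rate,
         disease_prevalences = disease_prevalences,
         coding_propensity = coding_propensity,
         variant_rate = variant_rate, misspell_rate = misspell_rate,
         invalid_mapping_rate = invalid_mapping_rate,
         historical_fraction = historical_fraction),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  seed %d | %d practices x %d patients | consult rate %.2f / window\n",
              x$seed, x$n_practices, x$patients_per_practice, x$consult_rate))
  cat(sprintf("  window %s .. %s | variant %.2f | misspell %.3f | historical %.2f\n",
              format(x$window$start), format(x$window$end),
              x$variant_rate, x$misspell_rate, x$historical_fraction))
  invisible(x)
}

#' Default per-disease prevalences, coding propensities and mapping-error rates
#'
#' `default_prevalences()` returns the validated-diagnosis proportions of the
#' published audit cohort; `default_coding_propensity()` returns per-disease
#' Beta shapes with mean equal to the audit's coded fraction and concentration
#' 10, giving the wide between-practice spread seen in practice-level data;
#' `default_invalid_mapping_rates()` returns the audit's reported
#' invalid-mapping exclusion rates.
#'
#' @return Named numeric vector (prevalences, rates) or named list of Beta
#'   shape pairs (propensities), one element per disease.
#' @export
default_prevalences <- function() {
  counts <- published_audit_counts()
  stats::setNames(counts$validated_n / counts$cohort_n, counts$disease)[DISEASES]
}

#' @rdname default_prevalences
#' @param concentration Beta concentration (shape1 + shape2) controlling
#'   between-practice spread; default 10.
#' @export
default_coding_propensity <- function(concentration = 10) {
  counts <- published_audit_counts()
  means <- stats::setNames(counts$coded_n / counts$validated_n, counts$disease)
  lapply(stats::setNames(DISEASES, DISEASES), function(d) {
    c(means[[d]] * concentration, (1 - means[[d]]) * concentration)
  })
}

#' @rdname default_prevalences
#' @export
default_invalid_mapping_rates <- function() {
  counts <- published_audit_counts()
  stats::setNames(
    counts$excluded_invalid_n / (counts$excluded_invalid_n + counts$coded_n),
    counts$disease
  )[DISEASES]
}

propensity_mean <- function(spec) {
  if (length(spec) == 1) spec else spec[1] / (spec[1] + spec[2])
}

#' Expected undercount of the generator, in percent
#'
#' Closed-form companion to [generate_cohort()]: the undercount percentage
#' the audit pipeline is expected to measure on a cohort generated under
#' `config`. With mean coding propensity `p` and uncoded-term match
#' probability `m = 1 - misspell_rate` (a typo never matches the validated
#' list), the expected undercount is `100 * (1 - p) * m / (p + (1 - p) * m)`.
#' Invalid-mapped entries are emitted for decoy patients who carry neither a
#' validated term nor a legitimate code for the disease, so they cancel from
#' both the coded and the validated count and need no further adjustment.
#'
#' @param config A [synth_config()].
#' @param disease One of [audit_diseases()].
#' @return Expected undercount percentage.
#' @export
expected_undercount <- function(config, disease) {
  if (!disease %in% DISEASES) stop(sprintf("unknown disease: %s", disease), call. = FALSE)
  p <- propensity_mean(config$coding_propensity[[disease]])
  m <- 1 - config$misspell_rate
  if (p + (1 - p) * m == 0) return(NA_real_)
  100 * (1 - p) * m / (p + (1 - p) * m)
}

#' Corrupt a canonical term into realistic free-text
#'
#' Emulates how clinicians type diagnoses: with probability `variant_rate`
#' the canonical term is replaced by one of the disease's listed
#' abbreviation/word-order variants; with probability `misspell_rate` the
#' resulting string then receives one random character edit (substitute,
#' delete, transpose or insert; lowercase). Both rates zero returns the
#' canonical term unchanged.
#'
#' @param canonical_term A canonical lookup term of `disease` (checked
#'   against the built-in lexicon).
#' @param disease One of [audit_diseases()].
#' @param config A [synth_config()] supplying `variant_rate` and
#'   `misspell_rate`.
#' @return A single free-text string. Uses the current RNG state.
#' @export
corrupt_term <- function(canonical_term, disease, config) {
  if (!disease %in% DISEASES) stop(sprintf("unknown disease: %s", disease), call. = FALSE)
  canon <- lexicon_codes()
  ok <- normalize_term(canonical_term) %in%
    normalize_term(canon$canonical_term[canon$disease == disease])
  if (!ok) {
    stop(sprintf("'%s' is not a canonical lookup term for %s", canonical_term, disease),
         call. = FALSE)
  }
  res <- corrupt_terms_vec(rep(canonical_term, 1), disease,
                           config$variant_rate, config$misspell_rate)
  res$term
}

# Vectorised corruption for n entries of one disease sharing a base term each.
corrupt_terms_vec <- function(base_terms, disease, variant_rate, misspell_rate) {
  n <- length(base_terms)
  variants <- lexicon_variants()
  pool <- variants$term[variants$disease == disease]
  use_variant <- runif(n) < variant_rate & length(pool) > 0
  out <- base_terms
  if (any(use_variant)) {
    out[use_variant] <- pool[sample.int(length(pool), sum(use_variant), replace = TRUE)]
  }
  misspell <- runif(n) < misspell_rate
  if (any(misspell)) {
    out[misspell] <- vapply(out[misspell], misspell_once, character(1), USE.NAMES = FALSE)
  }
  list(term = out, is_variant = use_variant, is_misspelt = misspell)
}

# One random character edit at OSA distance exactly 1 from tolower(term).
# Inserted/substituted characters are letters only, so an edit can never turn
# one validated term into another (e.g. "type 1 diabetes" into "type 2
# diabetes" would need a digit substitution).
misspell_once <- function(term) {
  s <- strsplit(tolower(term), "")[[1]]
  L <- length(s)
  ops <- c("substitute", "insert", if (L > 1) c("delete", "transpose"))
  op <- sample(ops, 1)
  if (op == "transpose") {
    pos <- which(s[-L] != s[-1])
    if (length(pos) == 0) op <- "substitute" else {
      i <- pos[sample.int(length(pos), 1)]
      s[c(i, i + 1)] <- s[c(i + 1, i)]
      return(paste(s, collapse = ""))
    }
  }
  if (op == "substitute") {
    i <- sample.int(L, 1)
    s[i] <- sample(setdiff(letters, s[i]), 1)
    return(paste(s, collapse = ""))
  }
  if (op == "delete") {
    i <- sample.int(L, 1)
    return(paste(s[-i], collapse = ""))
  }
  # insert
  i <- sample.int(L + 1, 1)
  paste(c(head(s, i - 1), sample(letters, 1), if (i <= L) s[i:L]), collapse = "")
}

#' Generate a synthetic EMR extract with ground truth
#'
#' Draws a multi-practice cohort under `config`: per-patient consultation
#' counts are Poisson, each practice draws one coding propensity per disease
#' (point mass or Beta), each truly diseased patient receives one diagnosis
#' entry per disease — coded with the practice's propensity (carrying the
#' code's canonical display term) or free-text (canonical term, listed
#' variant, or single-edit misspelling) — and, per disease, a small number of
#' decoy patients receive a wrongly mapped entry (the disease's code paired
#' with a term denoting a different condition) at the configured
#' invalid-mapping rate. Diagnosis dates fall inside the window or uniformly
#' in the ten years before it. Output is byte-identical for a fixed config.
#'
#' @param config A [synth_config()].
#' @return A list with elements `extract` (a validated [emr_extract()]) and
#'   `truth`: per-patient true diseases (`patients`), per-entry labels
#'   aligned row-for-row with `extract$diagnoses` (`entries`), and the
#'   realised per-practice coding propensities (`practice_propensity`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  P <- config$n_practices
  m <- config$patients_per_practice
  n <- P * m
  practices <- sprintf("PR%03d", seq_len(P))
  pat <- tibble::tibble(
    patient_id = sprintf("PT%07d", seq_len(n)),
    practice_id = rep(practices, each = m),
    birth_year = sample(1930:2005, n, replace = TRUE)
  )

  win <- config$window
  n_days <- as.integer(win$end - win$start) + 1L
  k <- rpois(n, config$consult_rate)
  idx <- rep.int(seq_len(n), k)
  enc <- tibble::tibble(
    patient_id = pat$patient_id[idx],
    practice_id = pat$practice_id[idx],
    date = win$start + (sample.int(n_days, length(idx), replace = TRUE) - 1L)
  )

  prop <- lapply(stats::setNames(DISEASES, DISEASES), function(d) {
    spec <- config$coding_propensity[[d]]
    if (length(spec) == 1) rep(spec, P) else rbeta(P, spec[1], spec[2])
  })
  practice_propensity <- tibble::tibble(
    practice_id = rep(practices, times = length(DISEASES)),
    disease = rep(DISEASES, each = P),
    propensity = unlist(prop, use.names = FALSE)
  )

  codes <- lexicon_codes()
  decoys <- lexicon_invalid_mappings()
  entry_parts <- list()
  truth_pat_parts <- list()
  for (d in DISEASES) {
    diseased <- which(runif(n) < config$disease_prevalences[[d]])
    nd <- length(diseased)
    truth_pat_parts[[d]] <- tibble::tibble(
      patient_id = pat$patient_id[diseased], disease = d
    )
    if (nd > 0) {
      prac_i <- ((diseased - 1L) %/% m) + 1L
      coded <- runif(nd) < prop[[d]][prac_i]
      d_codes <- codes[codes$disease == d, ]
      code_pick <- sample.int(nrow(d_codes), nd, replace = TRUE)
      term <- d_codes$canonical_term[code_pick]
      code <- ifelse(coded, d_codes$code[code_pick], "")
      is_variant <- is_misspelt <- rep(FALSE, nd)
      if (any(!coded)) {
        corr <- corrupt_terms_vec(term[!coded], d,
                                  config$variant_rate, config$misspell_rate)
        term[!coded] <- corr$term
        is_variant[!coded] <- corr$is_variant
        is_misspelt[!coded] <- corr$is_misspelt
      }
      entry_parts[[d]] <- tibble::tibble(
        pat_i = diseased, disease = d, code = code, term = term,
        coded = coded, is_variant = is_variant, is_misspelt = is_misspelt,
        is_invalid_mapping = FALSE
      )
    } else {
      coded <- logical(0)
    }
    # wrongly mapped entries: decoy patients who do not have the disease
    r <- config$invalid_mapping_rate[[d]]
    n_coded <- sum(coded)
    if (r > 0 && r < 1 && n_coded > 0) {
      n_inv <- rbinom(1, n_coded, r / (1 - r))
      candidates <- setdiff(seq_len(n), diseased)
      n_inv <- min(n_inv, length(candidates))
      if (n_inv > 0) {
        who <- sample(candidates, n_inv)
        decoy <- decoys[decoys$disease == d, ]
        entry_parts[[paste0(d, "_invalid")]] <- tibble::tibble(
          pat_i = who, disease = d, code = decoy$code[1], term = decoy$term[1],
          coded = TRUE, is_variant = FALSE, is_misspelt = FALSE,
          is_invalid_mapping = TRUE
        )
      }
    }
  }
  entries <- dplyr::bind_rows(entry_parts)

  n_e <- nrow(entries)
  historical <- runif(n_e) < config$historical_fraction
  hist_days <- 3652L
  date <- win$start + (sample.int(n_days, n_e, replace = TRUE) - 1L)
  date[historical] <- win$start - sample.int(hist_days, sum(historical), replace = TRUE)
  entries$date <- date

  entries$patient_id <- pat$patient_id[entries$pat_i]
  entries$practice_id <- pat$practice_id[entries$pat_i]
  ord <- order(entries$patient_id, entries$date, entries$code, entries$term,
               entries$disease)
  entries <- entries[ord, ]

  diagnoses <- entries[, c("patient_id", "practice_id", "date", "code", "term")]
  truth_entries <- entries[, c("patient_id", "practice_id", "disease", "coded",
                               "is_variant", "is_misspelt", "is_invalid_mapping")]
  truth_patients <- dplyr::arrange(dplyr::bind_rows(truth_pat_parts),
                                   .data$patient_id, .data$disease)

  extract <- emr_extract(pat, enc, diagnoses, code_system_label = "synthetic-lookup")
  list(
    extract = extract,
    truth = list(
      patients = truth_patients,
      entries = truth_entries,
      practice_propensity = practice_propensity,
      seed = config$seed
    )
  )
}

#' Write a generated cohort (extract, ground truth, config echo) to disk
#'
#' Emits the three extract CSVs, `ground_truth.csv` (per-entry labels) and a
#' YAML echo of the generating configuration.
#'
#' @param cohort Result of [generate_cohort()].
#' @param config The [synth_config()] that produced it.
#' @param dir Destination directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, config, dir) {
  write_extract(cohort$extract, dir)
  readr::write_csv(cohort$truth$entries, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$truth$patients, file.path(dir, "ground_truth_patients.csv"),
                   progress = FALSE)
  cfg <- config
  cfg$window <- list(start = format(cfg$window$start), end = format(cfg$window$end))
  yaml::write_yaml(lapply(unclass(cfg), function(x) if (is.numeric(x)) as.list(x) else x),
                   file.path(dir, "synth_config.yaml"))
  invisible(dir)
}
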