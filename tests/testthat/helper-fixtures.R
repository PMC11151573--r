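# Shared fixtures and independent oracles.

# Build a small extract from compact row specs. Every listed patient gets
# `n_consults` in-window encounters unless overridden.
make_extract <- function(diagnoses, patients = NULL, encounters = NULL,
                         n_consults = 3) {
  if (is.null(patients)) {
    ids <- unique(diagnoses$patient_id)
    patients <- tibble::tibble(
      patient_id = ids,
      practice_id = if ("practice_id" %in% names(diagnoses)) {
        diagnoses$practice_id[match(ids, diagnoses$patient_id)]
      } else "PR001",
      birth_year = NA_integer_
    )
  }
  if (!"practice_id" %in% names(diagnoses)) diagnoses$practice_id <- "PR001"
  if (!"date" %in% names(diagnoses)) diagnoses$date <- as.Date("2021-06-01")
  if (!"code" %in% names(diagnoses)) diagnoses$code <- ""
  if (is.null(encounters)) {
    encounters <- tidyr::crossing(
      patients[, c("patient_id", "practice_id")],
      date = as.Date("2021-02-01") + seq_len(n_consults) * 30
    )
  }
  emr_extract(patients, encounters, diagnoses)
}

# Dictionary built through the public CSV interface.
write_dict_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                              .local_envir = parent.frame())) {
  readr::write_csv(rows, path, progress = FALSE)
  path
}

dict_row <- function(disease, kind, code = "", term = "", status = "", note = "") {
  tibble::tibble(disease = disease, kind = kind, code = code, term = term,
                 status = status, note = note)
}

# A two-disease dictionary used by the engine unit tests: disease "x" has
# code K1 (canonical "term x"), disease "y" is text-only, and the pair
# (K1, "term y") is a known wrong mapping of a y term onto an x code.
toy_dict <- function() {
  load_dictionary(write_dict_csv(dplyr::bind_rows(
    dict_row("x", "code", code = "K1", term = "term x"),
    dict_row("x", "term", term = "x variant", status = "validated"),
    dict_row("y", "term", term = "term y", status = "validated"),
    dict_row("x", "invalid_mapping", code = "K1", term = "term y")
  ), path = withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())))
}

# Independent oracle: optimal string alignment (restricted Damerau-
# Levenshtein) distance, counting substitution, insertion, deletion and
# adjacent transposition each as one edit.
osa_dist <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- as.integer(a[i] != b[j])
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
      if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j]) {
        d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
      }
    }
  }
  d[n + 1, m + 1]
}

# Published audit counts, used throughout the statistics checks.
published <- function() published_audit_counts()

# A cohort_summary assembled from externally supplied counts (bypasses the
# counting engine so the stats layer can be fed published numbers).
summary_from_counts <- function(counts, N) {
  total <- counts |>
    dplyr::summarise(disease = "all", scope = "cohort",
                     A = sum(A), B = sum(B), C = sum(C),
                     excluded_invalid_n = sum(excluded_invalid_n))
  structure(list(N = N, counts = dplyr::bind_rows(counts, total)),
            class = "cohort_summary")
}

published_count_rows <- function() {
  pub <- published()
  tibble::tibble(
    disease = pub$disease, scope = "cohort",
    A = as.integer(pub$coded_n), B = as.integer(pub$validated_n),
    C = as.integer(pub$validated_n - pub$coded_n),
    excluded_invalid_n = as.integer(pub$excluded_invalid_n)
  )
}
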