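# Patient-level counting. For each disease:
#   A = active patients with >= 1 coded-match entry (coded-only definition),
#   B = active patients with >= 1 text-match entry (validated free-text with
#       or without a code),
#   C = B - A, the undercount.
# Diagnosis entries of any date are eligible: a historical diagnosis recorded
# before the active window still identifies the patient. Counting is
# patient-level, so duplicate diagnosis rows never change a count.

count_from_classified <- function(cls, diagnoses, active_set, disease, scope_col = NULL) {
  keep <- cls$disease == disease
  cls <- cls[keep, , drop = FALSE]
  pid <- diagnoses$patient_id[cls$entry]
  active <- pid %in% active_set
  cls <- cls[active, , drop = FALSE]
  pid <- pid[active]
  grp <- if (is.null(scope_col)) rep("cohort", length(pid)) else
    diagnoses[[scope_col]][cls$entry]
  df <- tibble::tibble(patient_id = pid, grp = grp,
                       coded = cls$coded_match, text = cls$text_match,
                       invalid = cls$excluded_invalid)
  per_pat <- df |>
    dplyr::group_by(.data$grp, .data$patient_id) |>
    dplyr::summarise(coded = any(.data$coded), text = any(.data$text),
                     invalid = any(.data$invalid), .groups = "drop")
  per_pat |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      A = sum(.data$coded),
      B = sum(.data$text),
      excluded_invalid_n = sum(.data$invalid & !.data$coded),
      .groups = "drop"
    ) |>
    dplyr::mutate(disease = disease, C = .data$B - .data$A)
}

count_row_shape <- function(rows) {
  out <- rows |>
    dplyr::transmute(disease = .data$disease, scope = .data$grp,
                     A = as.integer(.data$A), B = as.integer(.data$B),
                     C = as.integer(.data$C),
                     excluded_invalid_n = as.integer(.data$excluded_invalid_n))
  # structural guarantee: a coded match always implies a text match
  stopifnot(all(out$A <= out$B))
  out
}

#' Count patients for one disease
#'
#' Computes the coded-only count `A`, the validated free-text (with or
#' without code) count `B`, the undercount `C = B - A` and the number of
#' active patients excluded because their only coded-match candidates for
#' the disease were invalid mappings. Each patient contributes at most once
#' to each count; entries of non-active patients are ignored; entries of any
#' date (including before the active window) are eligible.
#'
#' @param extract An [emr_extract()].
#' @param active_set Character vector of active patient ids
#'   (see [active_patients()]).
#' @param dict A `phenotype_dictionary`.
#' @param disease One disease key present in the dictionary.
#' @param scope `"cohort"` for a single row, or `"practice"` for one row per
#'   practice (patients attributed to the practice of the diagnosis entry).
#' @return Tibble with columns `disease`, `scope`, `A`, `B`, `C`,
#'   `excluded_invalid_n`.
#' @export
count_disease <- function(extract, active_set, dict, disease, scope = "cohort") {
  if (!disease %in% unique(c(dict$codes$disease, dict$terms$disease))) {
    stop(sprintf("disease '%s' is absent from the dictionary", disease), call. = FALSE)
  }
  cls <- classify_entries(extract$diagnoses, dict)
  count_disease_classified(cls, extract, active_set, disease, scope)
}

count_disease_classified <- function(cls, extract, active_set, disease, scope) {
  scope_col <- if (scope == "practice") "practice_id" else NULL
  rows <- count_from_classified(cls, extract$diagnoses, active_set, disease, scope_col)
  if (nrow(rows) == 0 && scope == "cohort") {
    rows <- tibble::tibble(grp = "cohort", A = 0L, B = 0L,
                           excluded_invalid_n = 0L, disease = disease, C = 0L)
  }
  count_row_shape(rows)
}

#' Summarise a cohort across all dictionary diseases
#'
#' One [count_disease()] row per disease plus an `all` row holding the
#' column-wise sum: the all-diagnosis totals count a patient once per disease
#' they carry, so a patient with two diseases appears twice there.
#'
#' @inheritParams count_disease
#' @param diseases Diseases to audit; defaults to every disease in the
#'   dictionary, in [audit_diseases()] order where applicable.
#' @return A `cohort_summary`: list with `N` (number of active patients),
#'   `counts` (per-disease rows plus the `all` row).
#' @export
summarise_cohort <- function(extract, active_set, dict,
                             diseases = dictionary_diseases(dict)) {
  cls <- classify_entries(extract$diagnoses, dict)
  rows <- dplyr::bind_rows(lapply(diseases, function(d) {
    count_disease_classified(cls, extract, active_set, d, "cohort")
  }))
  total <- rows |>
    dplyr::summarise(disease = "all", scope = "cohort",
                     A = sum(.data$A), B = sum(.data$B), C = sum(.data$C),
                     excluded_invalid_n = sum(.data$excluded_invalid_n))
  structure(
    list(N = length(unique(active_set)), counts = dplyr::bind_rows(rows, total)),
    class = "cohort_summary"
  )
}

dictionary_diseases <- function(dict) {
  present <- unique(c(dict$codes$disease, dict$terms$disease))
  c(intersect(DISEASES, present), sort(setdiff(present, DISEASES)))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> N = %d active patients\n", x$N))
  print(x$counts)
  invisible(x)
}

#' Per-practice disease counts
#'
#' One count row per (practice, disease), with patients attributed to the
#' practice of the diagnosis entry. For cohorts where every patient attends
#' a single practice (as generated synthetically), the cohort row of each
#' disease equals the column-wise sum of its practice rows.
#'
#' @inheritParams summarise_cohort
#' @return Tibble of count rows with `scope` = practice id.
#' @export
per_practice_counts <- function(extract, active_set, dict,
                                diseases = dictionary_diseases(dict)) {
  cls <- classify_entries(extract$diagnoses, dict)
  dplyr::bind_rows(lapply(diseases, function(d) {
    count_disease_classified(cls, extract, active_set, d, "practice")
  }))
}
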