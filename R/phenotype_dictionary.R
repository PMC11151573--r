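#' Normalize a diagnosis term for matching
#'
#' Diagnosis-field strings are short and without linguistic structure, so the
#' only normalization applied before exact matching is casefolding, stripping
#' leading/trailing whitespace and collapsing internal whitespace runs to a
#' single space. Punctuation is preserved: hyphens and slashes distinguish
#' real terms, and curators list variants explicitly. The operation is
#' idempotent.
#'
#' @param raw Character vector of raw terms.
#' @return Character vector of normalized terms.
#' @export
#' @examples
#' normalize_term("  Type 2   Diabetes ")
normalize_term <- function(raw) {
  stringr::str_to_lower(stringr::str_squish(as.character(raw)))
}

new_phenotype_dictionary <- function(codes, terms, invalid) {
  structure(
    list(codes = codes, terms = terms, invalid_mappings = invalid),
    class = "phenotype_dictionary"
  )
}

validate_dictionary <- function(dict) {
  codes <- dict$codes; terms <- dict$terms; invalid <- dict$invalid_mappings
  dup <- terms |>
    dplyr::distinct(.data$disease, .data$term, .data$status) |>
    dplyr::count(.data$disease, .data$term) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf("conflicting status for term '%s' under disease '%s'",
                 dup$term[1], dup$disease[1]), call. = FALSE)
  }
  validated <- dplyr::filter(terms, .data$status == "validated")
  orphan_code <- dplyr::anti_join(
    codes, validated, by = c("disease", "canonical_term" = "term")
  )
  if (nrow(orphan_code) > 0) {
    stop(sprintf("code '%s' (%s) has no validated canonical lookup term",
                 orphan_code$code[1], orphan_code$disease[1]), call. = FALSE)
  }
  bad_pair <- dplyr::anti_join(invalid, codes, by = "code")
  if (nrow(bad_pair) > 0) {
    stop(sprintf("invalid-mapping pair references unknown code '%s'",
                 bad_pair$code[1]), call. = FALSE)
  }
  invisible(dict)
}

#' The built-in starter phenotype dictionary
#'
#' Returns the shipped six-disease dictionary: EMR code lists with their
#' canonical lookup terms, clinically validated free-text variants,
#' excluded-ambiguous terms, and known invalid (code, term) mappings. It is
#' the dictionary the synthetic-cohort generator assumes.
#'
#' @return A `phenotype_dictionary`: list of tibbles `codes` (disease, code,
#'   canonical_term), `terms` (disease, term, status) and `invalid_mappings`
#'   (disease, code, term). All terms are stored normalized.
#' @seealso [load_dictionary()], [write_dictionary()]
#' @export
default_dictionary <- function() {
  codes <- lexicon_codes() |>
    dplyr::mutate(canonical_term = normalize_term(.data$canonical_term))
  terms <- dplyr::bind_rows(
    codes |>
      dplyr::transmute(disease = .data$disease, term = .data$canonical_term,
                       status = "validated"),
    lexicon_variants() |>
      dplyr::transmute(disease = .data$disease, term = normalize_term(.data$term),
                       status = "validated"),
    lexicon_ambiguous() |>
      dplyr::transmute(disease = .data$disease, term = normalize_term(.data$term),
                       status = "excluded_ambiguous")
  ) |> dplyr::distinct()
  invalid <- lexicon_invalid_mappings() |>
    dplyr::mutate(term = normalize_term(.data$term))
  dict <- new_phenotype_dictionary(codes, terms, invalid)
  validate_dictionary(dict)
  dict
}

#' Load a phenotype dictionary from its CSV serialisation
#'
#' The file has columns `disease`, `kind` (`code` | `term` |
#' `invalid_mapping`), `code`, `term`, `status`, `note`. `code` rows bind a
#' lookup code to its canonical display term (stored as a validated term);
#' `term` rows carry curated free-text terms with status `validated` or
#' `excluded_ambiguous`; `invalid_mapping` rows list (code, term) pairs found
#' to be wrongly mapped. Terms are normalized on load. A term assigned two
#' different statuses for the same disease, or a code with no canonical term,
#' is an error.
#'
#' @param path Path to the dictionary CSV.
#' @return A `phenotype_dictionary`.
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop(sprintf("dictionary file not found: %s", path), call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("disease", "kind", "code", "term", "status")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop(sprintf("dictionary %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  raw$term <- normalize_term(raw$term)
  bad_kind <- setdiff(unique(raw$kind), c("code", "term", "invalid_mapping"))
  if (length(bad_kind) > 0) {
    stop(sprintf("unknown dictionary row kind: %s", bad_kind[1]), call. = FALSE)
  }
  code_rows <- dplyr::filter(raw, .data$kind == "code")
  if (any(is.na(code_rows$term) | !nzchar(code_rows$term))) {
    stop("a 'code' row must name the code's canonical lookup term", call. = FALSE)
  }
  codes <- code_rows |>
    dplyr::transmute(disease = .data$disease, code = .data$code,
                     canonical_term = .data$term)
  terms <- dplyr::bind_rows(
    code_rows |>
      dplyr::transmute(disease = .data$disease, term = .data$term,
                       status = "validated"),
    raw |>
      dplyr::filter(.data$kind == "term") |>
      dplyr::transmute(disease = .data$disease, term = .data$term,
                       status = .data$status)
  ) |> dplyr::distinct()
  bad_status <- setdiff(unique(terms$status), c("validated", "excluded_ambiguous"))
  if (length(bad_status) > 0) {
    stop(sprintf("unknown term status: %s", bad_status[1]), call. = FALSE)
  }
  invalid <- raw |>
    dplyr::filter(.data$kind == "invalid_mapping") |>
    dplyr::transmute(disease = .data$disease, code = .data$code, term = .data$term)
  dict <- new_phenotype_dictionary(codes, terms, invalid)
  validate_dictionary(dict)
  dict
}

#' Write a phenotype dictionary to its CSV serialisation
#'
#' @param dict A `phenotype_dictionary`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  rows <- dplyr::bind_rows(
    dict$codes |>
      dplyr::transmute(disease = .data$disease, kind = "code", code = .data$code,
                       term = .data$canonical_term, status = "validated", note = ""),
    dict$terms |>
      dplyr::anti_join(dict$codes, by = c("disease", "term" = "canonical_term")) |>
      dplyr::transmute(disease = .data$disease, kind = "term", code = "",
                       term = .data$term, status = .data$status, note = ""),
    dict$invalid_mappings |>
      dplyr::transmute(disease = .data$disease, kind = "invalid_mapping",
                       code = .data$code, term = .data$term, status = "", note = "")
  )
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' @export
print.phenotype_dictionary <- function(x, ...) {
  cat("<phenotype_dictionary>\n")
  cat(sprintf("  diseases: %s\n", paste(sort(unique(x$codes$disease)), collapse = ", ")))
  cat(sprintf("  codes: %d  validated terms: %d  excluded terms: %d  invalid mappings: %d\n",
              nrow(x$codes), sum(x$terms$status == "validated"),
              sum(x$terms$status == "excluded_ambiguous"), nrow(x$invalid_mappings)))
  invisible(x)
}

#' Classify diagnosis entries against a phenotype dictionary
#'
#' For every diagnosis entry and disease, determines (on exact matching of
#' normalized strings — no fuzzy matching):
#' \describe{
#'   \item{coded_match}{the entry's code belongs to the disease's code list
#'     and the (code, term) pair is not a known invalid mapping;}
#'   \item{text_match}{the entry's term is a clinically validated term for the
#'     disease, or the entry is a coded match (a non-invalid coded entry
#'     always displays a validated lookup term);}
#'   \item{excluded_invalid}{the (code, term) pair is listed as an invalid
#'     mapping, attributed to the disease of the code.}
#' }
#' By construction `excluded_invalid` forbids `coded_match`, and
#' `coded_match` implies `text_match`.
#'
#' @param diagnoses Tibble of diagnosis entries (columns `code`, `term`; other
#'   columns are carried through untouched).
#' @param dict A `phenotype_dictionary`.
#' @return A long tibble: one row per (entry, disease) with at least one flag
#'   set, with columns `entry` (row index into `diagnoses`), `disease`,
#'   `coded_match`, `text_match`, `excluded_invalid`.
#' @export
classify_entries <- function(diagnoses, dict) {
  n <- nrow(diagnoses)
  ent <- tibble::tibble(
    entry = seq_len(n),
    code = trimws(dplyr::coalesce(as.character(diagnoses$code), "")),
    term_norm = normalize_term(diagnoses$term)
  )
  inv <- dict$invalid_mappings |>
    dplyr::transmute(code = .data$code, term_norm = .data$term,
                     disease = .data$disease, excluded_invalid = TRUE)
  excl <- ent |>
    dplyr::inner_join(inv, by = c("code", "term_norm")) |>
    dplyr::select("entry", "disease", "excluded_invalid")
  coded <- ent |>
    dplyr::filter(nzchar(.data$code)) |>
    dplyr::inner_join(dplyr::select(dict$codes, "disease", "code"), by = "code") |>
    dplyr::anti_join(excl, by = c("entry", "disease")) |>
    dplyr::transmute(entry = .data$entry, disease = .data$disease, coded_match = TRUE)
  validated <- dict$terms |>
    dplyr::filter(.data$status == "validated") |>
    dplyr::transmute(term_norm = .data$term, disease = .data$disease)
  textm <- ent |>
    dplyr::inner_join(validated, by = "term_norm",
                      relationship = "many-to-many") |>
    dplyr::transmute(entry = .data$entry, disease = .data$disease, text_match = TRUE)
  out <- dplyr::full_join(coded, textm, by = c("entry", "disease")) |>
    dplyr::full_join(excl, by = c("entry", "disease")) |>
    dplyr::mutate(
      coded_match = dplyr::coalesce(.data$coded_match, FALSE),
      excluded_invalid = dplyr::coalesce(.data$excluded_invalid, FALSE),
      text_match = dplyr::coalesce(.data$text_match, FALSE) | .data$coded_match
    ) |>
    dplyr::arrange(.data$entry, .data$disease)
  out
}

#' @rdname classify_entries
#' @param entry A single diagnosis entry: list or one-row data frame with
#'   `code` and `term`.
#' @export
classify_entry <- function(entry, dict) {
  classify_entries(tibble::as_tibble(entry[c("code", "term")]), dict)
}

#' Harvest candidate free-text terms for curation
#'
#' Queries the diagnosis histories of an extract for every distinct
#' normalized term matching any of the supplied per-disease seed patterns,
#' and returns a curation worksheet ranked by patient frequency — the number
#' of distinct patients carrying the term, not the number of rows. The
#' worksheet's `status` column is left blank for expert review; the package
#' performs no automated curation.
#'
#' @param extract An [emr_extract()].
#' @param seed_patterns Named list: disease -> character vector of
#'   case-insensitive regular expressions matched against normalized terms.
#' @return Tibble with columns `term`, `n_patients`, `diseases` (semicolon
#'   -separated suggestions), `status` (blank), sorted by descending
#'   `n_patients` then term.
#' @export
harvest_candidate_terms <- function(extract, seed_patterns) {
  if (length(seed_patterns) == 0) {
    stop("no seed patterns supplied", call. = FALSE)
  }
  d <- extract$diagnoses |>
    dplyr::mutate(term_norm = normalize_term(.data$term)) |>
    dplyr::distinct(.data$patient_id, .data$term_norm)
  per_term <- d |> dplyr::count(.data$term_norm, name = "n_patients")
  hits <- lapply(names(seed_patterns), function(dis) {
    pat <- paste(seed_patterns[[dis]], collapse = "|")
    matched <- per_term$term_norm[stringr::str_detect(per_term$term_norm,
                                                      stringr::regex(pat, ignore_case = TRUE))]
    if (length(matched) == 0) return(NULL)
    tibble::tibble(term_norm = matched, disease = dis)
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0 || nrow(per_term) == 0) {
    return(tibble::tibble(term = character(), n_patients = integer(),
                          diseases = character(), status = character()))
  }
  hits |>
    dplyr::group_by(.data$term_norm) |>
    dplyr::summarise(diseases = paste(sort(unique(.data$disease)), collapse = ";"),
                     .groups = "drop") |>
    dplyr::inner_join(per_term, by = "term_norm") |>
    dplyr::transmute(term = .data$term_norm, n_patients = as.integer(.data$n_patients),
                     diseases = .data$diseases, status = "") |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$term)
}
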