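#' Construct an EMR extract
#'
#' An EMR extract bundles the three linked tables produced by a
#' general-practice data extraction: patients, encounters (consultations) and
#' diagnosis-history entries. A diagnosis entry always carries a display/free
#' -text term; it may additionally carry a code from the practice software's
#' lookup list. The reverse — a code with no term — cannot occur in the source
#' systems, and is rejected here.
#'
#' @param patients Data frame with columns `patient_id`, `practice_id` and
#'   optionally `birth_year`.
#' @param encounters Data frame with columns `patient_id`, `practice_id`,
#'   `date` (`Date` or ISO-8601 string).
#' @param diagnoses Data frame with columns `patient_id`, `practice_id`,
#'   `date`, `code` (empty string or `NA` = uncoded) and `term`.
#' @param code_system_label Label for the (opaque) code system the `code`
#'   column is drawn from.
#' @param check If `TRUE` (default), invariants are enforced and any
#'   violation is an error; see [validate_extract()] for a non-throwing report.
#'
#' @return An object of class `emr_extract`: a list with elements `patients`,
#'   `encounters`, `diagnoses` (tibbles) and `code_system_label`.
#' @seealso [read_extract()], [write_extract()], [validate_extract()]
#' @export
emr_extract <- function(patients, encounters, diagnoses,
                        code_system_label = "opaque", check = TRUE) {
  patients <- tibble::as_tibble(patients)
  encounters <- tibble::as_tibble(encounters)
  diagnoses <- tibble::as_tibble(diagnoses)
  if (!"birth_year" %in% names(patients)) patients$birth_year <- NA_integer_
  patients$birth_year <- as.integer(patients$birth_year)
  patients <- patients[, c("patient_id", "practice_id", "birth_year")]
  encounters <- encounters[, c("patient_id", "practice_id", "date")]
  diagnoses <- diagnoses[, c("patient_id", "practice_id", "date", "code", "term")]
  encounters$date <- parse_iso_date(encounters$date, "encounters")
  diagnoses$date <- parse_iso_date(diagnoses$date, "diagnoses")
  diagnoses$code <- dplyr::coalesce(as.character(diagnoses$code), "")
  for (col in c("patient_id", "practice_id")) {
    patients[[col]] <- as.character(patients[[col]])
    encounters[[col]] <- as.character(encounters[[col]])
    diagnoses[[col]] <- as.character(diagnoses[[col]])
  }
  diagnoses$term <- as.character(diagnoses$term)
  x <- structure(
    list(patients = patients, encounters = encounters, diagnoses = diagnoses,
         code_system_label = code_system_label),
    class = "emr_extract"
  )
  if (check) {
    rep <- validate_extract(x)
    if (nrow(rep) > 0) {
      stop("invalid EMR extract:\n", format_violations(rep), call. = FALSE)
    }
  }
  x
}

parse_iso_date <- function(x, table) {
  if (inherits(x, "Date")) return(x)
  out <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad) > 0) {
    stop(sprintf("unparseable date in %s at row %d: %s",
                 table, bad[1], as.character(x)[bad[1]]), call. = FALSE)
  }
  out
}

format_violations <- function(rep) {
  paste(sprintf("  - %s (n = %d): %s", rep$kind, rep$n, rep$detail),
        collapse = "\n")
}

#' Validate an EMR extract without raising
#'
#' Checks the extract's invariants and reports every violation found:
#' duplicate or missing patient identifiers, encounters or diagnoses that
#' reference no known patient (orphans), empty diagnosis terms, and diagnosis
#' rows carrying a code but no term (impossible in the source EMR systems,
#' so always a processing artefact).
#'
#' @param extract An [emr_extract()] (or a bare list with the same elements).
#' @return A tibble with columns `kind`, `n`, `detail`; zero rows when the
#'   extract satisfies every invariant. The input is never modified.
#' @export
validate_extract <- function(extract) {
  p <- extract$patients; e <- extract$encounters; d <- extract$diagnoses
  out <- list()
  add <- function(kind, n, detail) {
    if (n > 0) out[[length(out) + 1]] <<- tibble::tibble(kind = kind, n = n, detail = detail)
  }
  add("duplicate-patient-id", sum(duplicated(p$patient_id)),
      "patient_id must be unique within an extract")
  add("empty-practice-id", sum(is.na(p$practice_id) | !nzchar(p$practice_id)),
      "patients must carry a practice_id")
  add("no-practice", as.integer(nrow(p) > 0 && dplyr::n_distinct(p$practice_id) < 1),
      "extract must cover at least one practice")
  add("orphan-encounter", sum(!e$patient_id %in% p$patient_id),
      "encounter references a patient_id absent from the patients table")
  add("orphan-diagnosis", sum(!d$patient_id %in% p$patient_id),
      "diagnosis references a patient_id absent from the patients table")
  add("missing-encounter-date", sum(is.na(e$date)),
      "encounter dates must be valid ISO-8601 dates")
  add("missing-diagnosis-date", sum(is.na(d$date)),
      "diagnosis dates must be valid ISO-8601 dates")
  empty_term <- is.na(d$term) | !nzchar(trimws(d$term))
  has_code <- !is.na(d$code) & nzchar(trimws(d$code))
  add("code-without-term", sum(empty_term & has_code),
      "a coded diagnosis always carries its lookup term; a code-only row is impossible")
  add("empty-term", sum(empty_term & !has_code),
      "diagnosis term must be non-empty")
  if (length(out) == 0) {
    tibble::tibble(kind = character(), n = integer(), detail = character())
  } else {
    dplyr::bind_rows(out)
  }
}

extract_col_spec <- function() {
  list(
    patients = c("patient_id", "practice_id", "birth_year"),
    encounters = c("patient_id", "practice_id", "date"),
    diagnoses = c("patient_id", "practice_id", "date", "code", "term")
  )
}

#' Read an EMR extract from a directory of CSV files
#'
#' Expects `patients.csv`, `encounters.csv` and `diagnoses.csv` (RFC-4180
#' quoting, UTF-8, one header row, ISO-8601 dates, empty string = absent
#' code). Row order never affects downstream results.
#'
#' @param dir Directory containing the three files.
#' @param code_system_label Code-system label to attach; defaults to the value
#'   stored by [write_extract()] if its metadata file is present.
#' @return A validated [emr_extract()].
#' @export
read_extract <- function(dir, code_system_label = NULL) {
  spec <- extract_col_spec()
  tabs <- lapply(names(spec), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop(sprintf("missing extract file: %s", path), call. = FALSE)
    }
    tab <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    missing <- setdiff(spec[[nm]], names(tab))
    # birth_year is generator metadata and optional on input
    missing <- setdiff(missing, if (nm == "patients") "birth_year" else character())
    if (length(missing) > 0) {
      stop(sprintf("file %s is missing column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    tab
  })
  names(tabs) <- names(spec)
  if (is.null(code_system_label)) {
    meta_path <- file.path(dir, "extract_meta.yaml")
    code_system_label <- if (file.exists(meta_path)) {
      yaml::read_yaml(meta_path)$code_system_label
    } else "opaque"
  }
  emr_extract(tabs$patients, tabs$encounters, tabs$diagnoses,
              code_system_label = code_system_label)
}

#' Write an EMR extract to a directory of CSV files
#'
#' Writes `patients.csv`, `encounters.csv`, `diagnoses.csv` and a small
#' `extract_meta.yaml` carrying the code-system label. Reading the directory
#' back with [read_extract()] reproduces the extract up to row order.
#'
#' @param extract An [emr_extract()].
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_extract <- function(extract, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory %s", dir), call. = FALSE)
  readr::write_csv(extract$patients, file.path(dir, "patients.csv"), progress = FALSE)
  readr::write_csv(extract$encounters, file.path(dir, "encounters.csv"), progress = FALSE)
  readr::write_csv(extract$diagnoses, file.path(dir, "diagnoses.csv"), progress = FALSE)
  yaml::write_yaml(list(code_system_label = extract$code_system_label),
                   file.path(dir, "extract_meta.yaml"))
  invisible(dir)
}

#' @export
print.emr_extract <- function(x, ...) {
  cat("<emr_extract>\n")
  cat(sprintf("  practices:  %d\n", dplyr::n_distinct(x$patients$practice_id)))
  cat(sprintf("  patients:   %d\n", nrow(x$patients)))
  cat(sprintf("  encounters: %d\n", nrow(x$encounters)))
  cat(sprintf("  diagnoses:  %d (%d coded)\n", nrow(x$diagnoses),
              sum(nzchar(x$diagnoses$code))))
  cat(sprintf("  code system: %s\n", x$code_system_label))
  invisible(x)
}

# Canonical row order, used to compare extracts ignoring row order.
sort_extract <- function(extract) {
  extract$patients <- dplyr::arrange(extract$patients, .data$patient_id)
  extract$encounters <- dplyr::arrange(extract$encounters, .data$patient_id,
                                       .data$date, .data$practice_id)
  extract$diagnoses <- dplyr::arrange(extract$diagnoses, .data$patient_id,
                                      .data$date, .data$code, .data$term)
  extract
}
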