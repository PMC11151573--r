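#' Assemble an audit report
#'
#' Combines cohort-level and per-practice counts with the statistics module
#' into a single report object. Rows are ordered asthma, CKD, COPD, dementia,
#' T1DM, T2DM, then any further dictionary diseases, then the all-diagnosis
#' row. Every number in the report is recomputed from the stored counts by
#' the stats functions; the renderer adds no numbers of its own.
#'
#' @param summary A `cohort_summary` from [summarise_cohort()].
#' @param per_practice Per-practice count rows from [per_practice_counts()].
#' @param window The [active_window()] audited.
#' @param dictionary_label Short label describing the dictionary used.
#' @param seed Generating seed when the extract is synthetic, else `NULL`.
#' @return An `audit_report`: list with `meta`, `table` (per-disease stats),
#'   `per_practice` (per-practice stats).
#' @export
build_report <- function(summary, per_practice, window = active_window(),
                         dictionary_label = "built-in", seed = NULL) {
  counts <- summary$counts
  known <- c(setdiff(unique(counts$disease), "all"), "all")
  bad <- setdiff(unique(per_practice$disease), known)
  if (length(bad) > 0) {
    stop(sprintf("per-practice rows name a disease absent from the summary: %s",
                 bad[1]), call. = FALSE)
  }
  ord <- c(intersect(DISEASES, counts$disease),
           sort(setdiff(counts$disease, c(DISEASES, "all"))), "all")
  tab <- undercount_stats(counts, summary$N) |>
    dplyr::mutate(label = dplyr::coalesce(DISEASE_LABELS[.data$disease],
                                          ifelse(.data$disease == "all",
                                                 "All diagnosis types", .data$disease))) |>
    dplyr::arrange(match(.data$disease, ord)) |>
    dplyr::select("disease", "label", "A", "B", "C", "percent_undercount",
                  "z", "p", "excluded_invalid_n", "mapping_exclusion_pct")
  pp <- undercount_stats(per_practice, summary$N) |>
    dplyr::rename(practice_id = "scope") |>
    dplyr::arrange(.data$practice_id, match(.data$disease, ord))
  structure(
    list(
      meta = list(
        window_start = format(window$start), window_end = format(window$end),
        N = summary$N,
        n_practices = dplyr::n_distinct(per_practice$scope),
        dictionary = dictionary_label,
        seed = seed,
        empty_cohort = summary$N == 0
      ),
      table = tab,
      per_practice = pp
    ),
    class = "audit_report"
  )
}

#' @export
print.audit_report <- function(x, ...) {
  m <- x$meta
  cat("<audit_report>\n")
  cat(sprintf("  window %s .. %s | N = %d active patients | %d practices | dictionary: %s\n",
              m$window_start, m$window_end, m$N, m$n_practices, m$dictionary))
  if (isTRUE(m$empty_cohort)) cat("  NOTE: empty cohort (no active patients)\n")
  tab <- x$table
  cat(sprintf("  %-38s %8s %8s %8s %8s %8s %8s\n",
              "Disease", "A coded", "B valid", "C=B-A", "%under", "z", "p"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-38s %8d %8d %8d %8s %8s %8s\n",
                tab$label[i], tab$A[i], tab$B[i], tab$C[i],
                ifelse(is.na(tab$percent_undercount[i]), "-",
                       sprintf("%.2f", tab$percent_undercount[i])),
                ifelse(is.na(tab$z[i]), "-", sprintf("%.2f", tab$z[i])),
                format_p_value(tab$p[i])))
  }
  invisible(x)
}

#' Write an audit report to disk
#'
#' Emits `audit_table.csv` (per-disease counts and statistics, unrounded),
#' `per_practice.csv`, and a human-readable `report.md` with the table
#' rendered to display precision (two decimals; p below 0.001 as
#' `"< 0.001"`). Output is deterministic: rewriting the same report is
#' byte-identical.
#'
#' @param report An `audit_report`.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$table, file.path(dir, "audit_table.csv"), progress = FALSE)
  readr::write_csv(report$per_practice, file.path(dir, "per_practice.csv"),
                   progress = FALSE)
  md <- render_report_md(report)
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

render_report_md <- function(report) {
  m <- report$meta
  tab <- report$table
  fmt <- function(x, digits = 2) ifelse(is.na(x), "-", sprintf(paste0("%.", digits, "f"), x))
  header <- c(
    "# Diagnosis undercount audit",
    "",
    sprintf("- Active window: %s to %s (inclusive)", m$window_start, m$window_end),
    sprintf("- Active patients (N): %d", m$N),
    sprintf("- Practices: %d", m$n_practices),
    sprintf("- Dictionary: %s", m$dictionary),
    if (!is.null(m$seed)) sprintf("- Synthetic seed: %d", m$seed),
    if (isTRUE(m$empty_cohort)) "- WARNING: empty cohort, all counts zero",
    "",
    "| Disease | A (coded) | B (validated) | C = B - A | % undercount | z | p | excluded (invalid mapping) | exclusion % |",
    "|---|---|---|---|---|---|---|---|---|"
  )
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    sprintf("| %s | %d | %d | %d | %s | %s | %s | %d | %s |",
            tab$label[i], tab$A[i], tab$B[i], tab$C[i],
            fmt(tab$percent_undercount[i]), fmt(tab$z[i]),
            format_p_value(tab$p[i]), tab$excluded_invalid_n[i],
            fmt(tab$mapping_exclusion_pct[i]))
  }, character(1))
  c(header, rows)
}

#' Read an audit report back from its CSV artifacts
#'
#' @param dir Directory written by [write_report()].
#' @return List with `table` and `per_practice` tibbles.
#' @export
read_report_csv <- function(dir) {
  list(
    table = readr::read_csv(file.path(dir, "audit_table.csv"),
                            col_types = readr::cols(), progress = FALSE),
    per_practice = readr::read_csv(file.path(dir, "per_practice.csv"),
                                   col_types = readr::cols(), progress = FALSE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file may name either a synthetic cohort (`synthetic:` block with
#' [synth_config()] fields, `seed` mandatory) or an input extract directory
#' (`input_dir:`), plus optional `dictionary:` (path to a dictionary CSV;
#' default the built-in dictionary) and `window:` (`start`, `end`).
#'
#' @param path Path to the YAML config.
#' @return A config list accepted by [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$synthetic) && is.null(cfg$input_dir)) {
    stop("config must name either a 'synthetic' block or an 'input_dir'", call. = FALSE)
  }
  cfg
}

#' Run the full audit pipeline
#'
#' Executes generate-or-read, validate, active-patient filter, classify,
#' count, statistics and report assembly, logging record counts per stage to
#' stderr. Deterministic given the configuration (and seed, when synthetic).
#'
#' @param config Config list (see [read_pipeline_config()]): either
#'   `config$synthetic` (list of [synth_config()] arguments; `seed` may sit
#'   there or at the top level) or `config$input_dir`; optional
#'   `config$dictionary` and `config$window`.
#' @param out_dir Optional directory; when given, the report artifacts (and
#'   the generated cohort, when synthetic) are written under it.
#' @return The `audit_report`, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  log_stage <- function(...) message("[emraudit] ", sprintf(...))
  window <- if (!is.null(config$window)) {
    active_window(config$window$start, config$window$end)
  } else {
    active_window()
  }
  dict_label <- "built-in"
  dict <- if (!is.null(config$dictionary)) {
    dict_label <- config$dictionary
    load_dictionary(config$dictionary)
  } else {
    default_dictionary()
  }
  seed <- NULL
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (is.null(args$seed)) args$seed <- config$seed
    if (is.null(args$seed)) stop("a seed is mandatory for synthetic runs", call. = FALSE)
    args$window <- window
    scfg <- do.call(synth_config, args)
    seed <- scfg$seed
    log_stage("stage synth: generating cohort (seed %d)", seed)
    cohort <- generate_cohort(scfg)
    extract <- cohort$extract
    if (!is.null(out_dir)) {
      write_cohort(cohort, scfg, file.path(out_dir, "cohort"))
    }
  } else {
    log_stage("stage read: %s", config$input_dir)
    extract <- read_extract(config$input_dir)
  }
  log_stage("stage read/synth: %d patients, %d encounters, %d diagnoses",
            nrow(extract$patients), nrow(extract$encounters), nrow(extract$diagnoses))
  rep <- validate_extract(extract)
  if (nrow(rep) > 0) {
    stop("stage validate: extract invalid:\n", format_violations(rep), call. = FALSE)
  }
  log_stage("stage validate: ok")
  active <- active_patients(extract, window)
  log_stage("stage active-filter: %d of %d patients active", length(active),
            nrow(extract$patients))
  summary <- summarise_cohort(extract, active, dict)
  log_stage("stage count: %d disease rows", nrow(summary$counts) - 1L)
  pp <- per_practice_counts(extract, active, dict)
  log_stage("stage per-practice: %d rows", nrow(pp))
  report <- build_report(summary, pp, window, dictionary_label = dict_label,
                         seed = seed)
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    log_stage("stage report: written to %s", out_dir)
  }
  invisible(report)
}
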