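#' Published per-disease audit counts
#'
#' Headline patient counts from a published data-quality audit of 84
#' Australian general practices (456,125 active patients): per disease, the
#' number of patients with a coded diagnosis (`coded_n`), the number with a
#' clinically validated free-text diagnosis with or without a code
#' (`validated_n`), the number of patients excluded because their coded entry
#' was an invalid code-term mapping (`excluded_invalid_n`), and the active
#' cohort size (`cohort_n`). These counts anchor the synthetic generator's
#' default prevalences, coding propensities and mapping-error rates, and let
#' the statistics module be checked against independently reported values.
#'
#' @return Tibble with one row per disease, in reporting order.
#' @export
published_audit_counts <- function() {
  path <- system.file("extdata", "published_counts.csv", package = "emraudit",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = "ccdddd", progress = FALSE)
}
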