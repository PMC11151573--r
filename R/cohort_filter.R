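#' Define the active-patient window
#'
#' The audit counts "active" patients in the sense used for Australian
#' general-practice reporting: three or more consultations in a two-year
#' period. Both endpoint dates are part of the period.
#'
#' @param start,end Window boundaries (`Date` or ISO-8601 strings). Defaults
#'   to the two calendar years 2021-2022.
#' @return An `active_window` object (list with `start`, `end`).
#' @export
active_window <- function(start = "2021-01-01", end = "2022-12-31") {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("window dates must be ISO-8601", call. = FALSE)
  if (start > end) stop("window start must not be after its end", call. = FALSE)
  two_years <- seq(start, by = "2 years", length.out = 2)[2] - 1
  if (end != two_years) {
    warning(sprintf("active window %s..%s does not span two years; the ≥3-consultation rule is defined over a two-year period",
                    format(start), format(end)), call. = FALSE)
  }
  structure(list(start = start, end = end), class = "active_window")
}

#' @export
print.active_window <- function(x, ...) {
  cat(sprintf("<active_window> %s .. %s (inclusive)\n", format(x$start), format(x$end)))
  invisible(x)
}

#' Identify active patients
#'
#' A patient is active when they have three or more consultation (encounter)
#' rows dated inside the window, boundaries inclusive. Consultations are
#' counted as rows: repeat consultations on the same day each count, since
#' the definition counts consultations, not days. Diagnosis entries play no
#' part — a historical diagnosis never makes a patient active.
#'
#' @param extract An [emr_extract()].
#' @param window An [active_window()].
#' @param min_consults Minimum in-window consultations; default 3.
#' @return Character vector of active `patient_id`s (sorted).
#' @export
active_patients <- function(extract, window = active_window(), min_consults = 3) {
  e <- extract$encounters
  inwin <- e[!is.na(e$date) & e$date >= window$start & e$date <= window$end, ]
  counts <- dplyr::count(inwin, .data$patient_id)
  sort(counts$patient_id[counts$n >= min_consults])
}
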