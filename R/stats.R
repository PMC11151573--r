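#' Percentage undercount
#'
#' The share of patients with a validated diagnosis who would be missed by a
#' coded-only count: `100 * (B - A) / B`, where `A` is the coded-only patient
#' count and `B` the validated free-text (with or without code) count.
#' Undefined when `B = 0` (returned as `NA` and excluded from practice
#' distributions). Values are unrounded; tables render to two decimals.
#'
#' @param row A count row from [count_disease()] (or any list with `A`, `B`),
#'   or a numeric `A` when `B` is given.
#' @param B Optional validated count, when `row` is given as the coded count.
#' @return Numeric percentage in `[0, 100]`, or `NA` when `B = 0`.
#' @export
#' @examples
#' percent_undercount(46853, 74038) # 36.72 at two decimals
percent_undercount <- function(row, B = NULL) {
  if (is.null(B)) {
    A <- row$A; B <- row$B
  } else {
    A <- row
  }
  out <- 100 * (B - A) / B
  out[B == 0] <- NA_real_
  out
}

#' Pooled two-proportion z statistic
#'
#' Tests the difference between the coded-only proportion `a/n` and the
#' validated proportion `b/n` in a cohort of `n` active patients, using the
#' pooled estimate `p = (a + b) / (2n)`:
#' `z = (b/n - a/n) / sqrt(p * (1 - p) * (2/n))`. The two proportions are
#' treated as independent samples of size `n` each, which is the convention
#' of the audit this package reproduces even though the two groups share
#' patients (a paired test would be more conservative; see the methods
#' vignette). Undefined (`NA`) when the pooled proportion is 0 or 1.
#'
#' @param a,b Patient counts (coded-only, validated).
#' @param n Cohort size.
#' @return The z statistic (unrounded).
#' @export
#' @examples
#' two_proportion_z(8303, 10721, 456125) # 17.72 at two decimals
two_proportion_z <- function(a, b, n) {
  stopifnot(all(n > 0), all(a >= 0), all(b >= 0), all(a <= n), all(b <= n))
  p1 <- a / n
  p2 <- b / n
  pooled <- (a + b) / (2 * n)
  v <- pooled * (1 - pooled) * (2 / n)
  out <- (p2 - p1) / sqrt(v)
  out[v == 0] <- NA_real_
  out
}

#' Two-sided p-value for a z statistic
#'
#' `p = 2 * (1 - pnorm(|z|))`. Tables render values below 0.001 as
#' `"< 0.001"`, otherwise to three decimals.
#'
#' @param z z statistic(s).
#' @return Two-sided normal tail probability.
#' @export
z_p_value <- function(z) {
  2 * pnorm(-abs(z))
}

format_p_value <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p)))
}

#' Invalid-mapping exclusion percentage
#'
#' Of the patients that a coded-only count would have picked up for a
#' disease, the share whose coded entries were wrong mappings and were
#' excluded: `100 * excluded / (excluded + retained_A)`.
#'
#' @param excluded Patients excluded as invalid-mapped.
#' @param retained_A Patients retained in the coded-only count.
#' @return Percentage, `NA` when both are zero.
#' @export
#' @examples
#' mapping_exclusion_pct(57, 2153) # 2.58 at two decimals
mapping_exclusion_pct <- function(excluded, retained_A) {
  stopifnot(all(excluded >= 0), all(retained_A >= 0))
  tot <- excluded + retained_A
  out <- 100 * excluded / tot
  out[tot == 0] <- NA_real_
  out
}

#' Undercount statistics for a set of count rows
#'
#' Attaches the percentage undercount, pooled z and two-sided p to each count
#' row, against a common cohort size `N`.
#'
#' @param counts Tibble of count rows (see [count_disease()]).
#' @param N Cohort size (number of active patients).
#' @return The input with columns `percent_undercount`, `z`, `p`,
#'   `mapping_exclusion_pct` appended.
#' @export
undercount_stats <- function(counts, N) {
  counts |>
    dplyr::mutate(
      percent_undercount = percent_undercount(.data$A, .data$B),
      z = if (N > 0) two_proportion_z(.data$A, .data$B, N) else NA_real_,
      p = z_p_value(.data$z),
      mapping_exclusion_pct = mapping_exclusion_pct(.data$excluded_invalid_n, .data$A)
    )
}

#' Distribution of per-practice undercount for one disease
#'
#' Summarises the spread of undercount percentages across practices as a
#' Tukey boxplot: median and quartiles by linear interpolation
#' (`quantile(type = 7)`), whiskers at the most extreme values within
#' 1.5 * IQR of the quartiles, values beyond the whiskers listed as
#' outliers. Practices with `B = 0` (undercount undefined) are excluded and
#' reported in `n_undefined`.
#'
#' @param practice_rows Per-practice count rows for one disease
#'   (see [per_practice_counts()]).
#' @param disease Disease key to summarise.
#' @return A list of class `practice_distribution`: disease, `n_practices`
#'   (with defined undercount), `n_undefined`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, and `outliers` (tibble of practice id and
#'   value). `NULL` statistics when no practice has a defined undercount.
#' @export
practice_distribution <- function(practice_rows, disease) {
  rows <- practice_rows[practice_rows$disease == disease, , drop = FALSE]
  val <- percent_undercount(rows$A, rows$B)
  defined <- !is.na(val)
  v <- val[defined]
  out <- list(disease = disease, n_practices = sum(defined),
              n_undefined = sum(!defined))
  if (length(v) == 0) {
    out <- c(out, list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                       whisker_low = NA_real_, whisker_high = NA_real_,
                       outliers = tibble::tibble(practice_id = character(),
                                                 value = numeric())))
    return(structure(out, class = "practice_distribution"))
  }
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- v >= lo_fence & v <= hi_fence
  outlier <- !inside
  out$median <- q[2]; out$q1 <- q[1]; out$q3 <- q[3]
  out$whisker_low <- min(v[inside])
  out$whisker_high <- max(v[inside])
  out$outliers <- tibble::tibble(
    practice_id = rows$scope[defined][outlier],
    value = v[outlier]
  )
  structure(out, class = "practice_distribution")
}

#' @export
print.practice_distribution <- function(x, ...) {
  cat(sprintf("<practice_distribution> %s: %d practices (%d undefined)\n",
              x$disease, x$n_practices, x$n_undefined))
  cat(sprintf("  median %.2f  [Q1 %.2f, Q3 %.2f]  whiskers [%.2f, %.2f]  outliers: %d\n",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
              nrow(x$outliers)))
  invisible(x)
}
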