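# Out-of-pocket expenditure aggregation: per-combination means with t-based
# confidence intervals, and the precision-based sample-size calculation.

#' Summarize out-of-pocket expenditure by treatment combination
#'
#' Aggregates per-patient course totals into per-combination means with 95%
#' t-intervals (`mean +/- t(n-1, 0.975) * SE`), reported both including and
#' excluding direct non-health spending (transport, boarding, food). The
#' cohort label (prospective daily interviews vs retrospective follow-up
#' interviews) is inert in estimation: both cohorts are pooled, as each
#' record already carries a per-course total. Pre-hospital spending is
#' summarized on its own line, never added into combination totals.
#'
#' @param records a `patient_records` data.frame (see
#'   [generate_patient_records()] or [read_patient_csv()]).
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return object of class `oop_summary`: data.frame with one row per
#'   combination plus a `pre_hospital` row, and columns `n`,
#'   `mean_incl_non_health`, `incl_ci_low`, `incl_ci_high`,
#'   `mean_excl_non_health`, `excl_ci_low`, `excl_ci_high`.
#' @export
summarize_oop <- function(records, conf_level = 0.95) {
  if (is.null(records) || nrow(records) == 0) {
    stop("empty input: no patient expenditure records to summarize",
         call. = FALSE)
  }
  assert_that(conf_level > 0 && conf_level < 1,
              "conf_level must lie in (0, 1)")

  mean_ci <- function(x) {
    n <- length(x)
    m <- mean(x)
    if (n < 2 || stats::sd(x) == 0) return(c(mean = m, low = m, high = m))
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(x) / sqrt(n)
    c(mean = m, low = m - half, high = m + half)
  }

  excl <- records$direct_health_total
  incl <- excl + records$direct_non_health_total

  rows <- lapply(sort(unique(records$combination)), function(cmb) {
    sel <- records$combination == cmb
    i <- mean_ci(incl[sel]); e <- mean_ci(excl[sel])
    data.frame(
      combination = cmb, n = sum(sel),
      mean_incl_non_health = i[["mean"]],
      incl_ci_low = i[["low"]], incl_ci_high = i[["high"]],
      mean_excl_non_health = e[["mean"]],
      excl_ci_low = e[["low"]], excl_ci_high = e[["high"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)

  if (!is.null(records$pre_hospital)) {
    p <- mean_ci(records$pre_hospital)
    out <- rbind(out, data.frame(
      combination = "pre_hospital", n = nrow(records),
      mean_incl_non_health = p[["mean"]],
      incl_ci_low = p[["low"]], incl_ci_high = p[["high"]],
      mean_excl_non_health = p[["mean"]],
      excl_ci_low = p[["low"]], excl_ci_high = p[["high"]],
      stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  class(out) <- c("oop_summary", "data.frame")
  out
}

#' Sample size for estimating a mean to a given precision
#'
#' Standard precision-based calculation: the number of patients needed to
#' estimate a mean expenditure within `precision` (absolute, INR) at the
#' given confidence level, assuming a known standard deviation:
#' `ceil((z * sd / precision)^2)`, with a floor of 1.
#'
#' @param sd assumed standard deviation of the expenditure, INR.
#' @param precision half-width of the desired confidence interval, INR.
#' @param confidence confidence level (default 0.95, giving z = 1.96).
#' @return required sample size (integer, >= 1).
#' @examples
#' required_sample_size(sd = 412, precision = 40)  # 408
#' @export
required_sample_size <- function(sd, precision, confidence = 0.95) {
  assert_that(sd >= 0, "sd must be >= 0")
  assert_that(precision > 0, "precision must be > 0")
  assert_that(confidence > 0 && confidence < 1,
              "confidence must lie in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  max(1L, as.integer(ceiling((z * sd / precision)^2)))
}
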