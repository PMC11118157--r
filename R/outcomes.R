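#' Round half away from zero
#'
#' Commercial rounding (18.75 -> 19, -6.67 -> -7), used to reproduce the
#' printed integer relative-PASI values; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Relative PASI improvement in percent
#'
#' `(before - after) / before * 100`: the percent reduction of the absolute
#' PASI from day 0. "PASI 90" in the clinical sense corresponds to a value of
#' 90. Negative values mean worsening.
#'
#' @param before Absolute PASI at day 0; must be positive.
#' @param after Absolute PASI at the outcome time.
#' @return Percent improvement, vectorised.
#' @export
#' @examples
#' relative_pasi_improvement(3.2, 2.6)           # 18.75
#' round_half_away(relative_pasi_improvement(3.2, 2.6))  # 19
relative_pasi_improvement <- function(before, after) {
  if (any(!is.na(before) & before <= 0)) {
    stop("relative PASI improvement is undefined for a zero day-0 PASI",
         call. = FALSE)
  }
  (before - after) / before * 100
}

#' PASI change quantities for one course
#'
#' Computes the PASI change in the same orientation as the biomarker change
#' quantities: `rate = (after - before) / before` and
#' `difference = after - before`, so a negative value means clinical
#' improvement. The familiar percent improvement is carried alongside
#' (`rate = -relative_improvement_pct / 100`).
#'
#' @param before Absolute PASI at day 0 (positive).
#' @param after Absolute PASI at the outcome time.
#' @return Tibble with columns `rate`, `difference`,
#'   `relative_improvement_pct`.
#' @export
#' @examples
#' pasi_change(13, 0.5)   # rate -0.9615, difference -12.5
pasi_change <- function(before, after) {
  pct <- relative_pasi_improvement(before, after)
  tibble::tibble(
    rate = (after - before) / before,
    difference = after - before,
    relative_improvement_pct = pct
  )
}

#' Per-course PASI change table for a cohort
#'
#' @param ds A [cohort_dataset()].
#' @return Tibble keyed on (`patient_id`, `biologic`) with the [pasi_change()]
#'   columns.
#' @export
pasi_change_table <- function(ds) {
  stopifnot(inherits(ds, "pso_cohort"))
  co <- ds$courses
  dplyr::bind_cols(
    tibble::tibble(patient_id = co$patient_id, biologic = co$biologic),
    pasi_change(co$pasi_before, co$pasi_after)
  )
}

#' Select the outcome PASI for a course under the timing rule
#'
#' The outcome PASI is the score closest in time to the PBMC test when the
#' patient had been on the biologic for at least 180 days at testing;
#' otherwise (inexperienced, or experienced under 180 days) it is the score
#' at day 180, falling back to the closest recorded month at or after month 6
#' when no exact day-180 score exists.
#'
#' @param months_on_drug_at_test Months the patient had been on this biologic
#'   when the PBMC sample was drawn (0 for a biologic started after testing).
#' @param pasi_series Data frame with columns `month` and `pasi`: the
#'   recorded PASI trajectory on this biologic.
#' @return The selected absolute PASI value.
#' @export
#' @examples
#' select_outcome_pasi(10, data.frame(month = c(6, 10), pasi = c(4.0, 2.6)))  # 2.6
#' select_outcome_pasi(2, data.frame(month = c(6, 12), pasi = c(1.0, 0.5)))   # 1.0
select_outcome_pasi <- function(months_on_drug_at_test, pasi_series) {
  stopifnot(is.data.frame(pasi_series),
            all(c("month", "pasi") %in% names(pasi_series)))
  if (nrow(pasi_series) == 0) stop("empty PASI series", call. = FALSE)
  if (any(pasi_series$month < 0) || months_on_drug_at_test < 0) {
    stop("months must be non-negative", call. = FALSE)
  }
  if (months_on_drug_at_test >= 6) {
    i <- which.min(abs(pasi_series$month - months_on_drug_at_test))
  } else {
    at_or_after <- which(pasi_series$month >= 6)
    i <- if (length(at_or_after)) {
      at_or_after[which.min(pasi_series$month[at_or_after])]
    } else {
      # no record at or past day 180: fall back to the latest available
      which.max(pasi_series$month)
    }
  }
  pasi_series$pasi[i]
}
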