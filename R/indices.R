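#' Parse a biomarker index definition
#'
#' An index is either a single analyte (`"IFN-g"`) or a ratio of two analytes
#' (`"IFN-g/IL-13"`). Ratios of a Th1/Th17 analyte over a Th2 analyte are the
#' study's headline biomarkers. Greek and alias spellings are accepted.
#'
#' @param x Index string.
#' @return List with `label` (canonical), `numerator`, `denominator`
#'   (`NA` for a single-analyte index), class `"pso_index"`.
#' @export
#' @examples
#' parse_index("IFN-γ/IL13")$label
parse_index <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  parts <- trimws(strsplit(x, "/", fixed = TRUE)[[1]])
  # "MIP-1a"-style names contain no slash, so a slash always separates the
  # numerator and denominator
  if (length(parts) > 2 || any(parts == "")) {
    stop(sprintf("cannot parse index %s: expected 'analyte' or 'analyte/analyte'",
                 shQuote(x)), call. = FALSE)
  }
  # tolerate "IL13" style without hyphen
  dehyph <- function(s) {
    if (grepl("^(IL|il)[0-9]+[A-Za-z]?$", s)) sub("^(IL|il)", "IL-", s) else s
  }
  parts <- normalize_analyte(vapply(parts, dehyph, character(1)))
  if (length(parts) == 2 && parts[1] == parts[2]) {
    stop("index numerator and denominator must differ", call. = FALSE)
  }
  structure(
    list(
      label = paste(parts, collapse = "/"),
      numerator = parts[1],
      denominator = if (length(parts) == 2) parts[2] else NA_character_
    ),
    class = "pso_index"
  )
}

#' Default and headline biomarker index sets
#'
#' `headline_indices()` returns the six biomarkers reported as representative
#' of treatment effectiveness: IFN-g, IL-13, and the four Th1/Th17-over-Th2
#' ratios. `default_indices()` adds IL-4, IL-17A and IL-6 to cover the full
#' correlation-table row set.
#'
#' @return Character vector of index labels.
#' @export
headline_indices <- function() {
  c("IFN-g", "IL-13", "IFN-g/IL-4", "IFN-g/IL-13", "IL-17A/IL-4", "IL-17A/IL-13")
}

#' @rdname headline_indices
#' @export
default_indices <- function() {
  c("IFN-g", "IL-13", "IL-4", "IL-17A", "IL-6",
    "IFN-g/IL-13", "IFN-g/IL-4", "IL-17A/IL-13", "IL-17A/IL-4")
}

#' Evaluate one index on one analyte panel
#'
#' @param panel Data frame with columns `analyte`, `concentration_pg_ml`,
#'   `censor` — one culture condition's measurements.
#' @param index Index string or [parse_index()] result.
#' @return List with `value` (numeric, `NA` when censored) and `status`
#'   (`"complete"` or `"censored"`). A below-range reading in either the
#'   numerator or the denominator censors the result.
#' @export
#' @examples
#' panel <- data.frame(
#'   analyte = c("IFN-g", "IL-13"),
#'   concentration_pg_ml = c(13.72, 4.19),
#'   censor = "observed"
#' )
#' compute_index_value(panel, "IFN-g/IL-13")$value  # 3.27 at 2 dp
compute_index_value <- function(panel, index) {
  if (!inherits(index, "pso_index")) index <- parse_index(index)
  panel$analyte <- normalize_analyte(panel$analyte)
  need <- c(index$numerator, if (!is.na(index$denominator)) index$denominator)
  pos <- match(need, panel$analyte)
  if (anyNA(pos)) {
    stop(sprintf("panel is missing analyte(s): %s",
                 paste(need[is.na(pos)], collapse = ", ")), call. = FALSE)
  }
  if (any(panel$censor[pos] == "below_range")) {
    return(list(value = NA_real_, status = "censored"))
  }
  conc <- panel$concentration_pg_ml[pos]
  if (is.na(index$denominator)) {
    return(list(value = conc[1], status = "complete"))
  }
  if (conc[2] == 0) {
    stop(sprintf("degenerate index %s: observed denominator is exactly 0",
                 index$label), call. = FALSE)
  }
  list(value = conc[1] / conc[2], status = "complete")
}

#' Reduction rate of an index under biologic treatment
#'
#' The relative change of an index between the S. pyogenes-induced baseline
#' and the induced+biologic condition: `(treated - baseline) / baseline`.
#' Negative values mean the biologic suppressed the index.
#'
#' @param baseline Index value under the induced-only condition; must be
#'   non-zero.
#' @param treated Index value under the induced+biologic condition.
#' @return `(treated - baseline) / baseline`, vectorised.
#' @seealso [reduction_difference()]
#' @export
#' @examples
#' reduction_rate(45.8, 33.41)  # -0.2705
reduction_rate <- function(baseline, treated) {
  stopifnot(length(baseline) == length(treated) || length(baseline) == 1 ||
              length(treated) == 1)
  if (any(!is.na(baseline) & baseline == 0)) {
    stop("reduction_rate is undefined for a zero baseline", call. = FALSE)
  }
  (treated - baseline) / baseline
}

#' Reduction difference of an index under biologic treatment
#'
#' The absolute change `treated - baseline`, in index units.
#'
#' @inheritParams reduction_rate
#' @return `treated - baseline`, vectorised.
#' @export
reduction_difference <- function(baseline, treated) {
  treated - baseline
}

#' Build the per-course index change table
#'
#' For every patient-biologic course and every requested index, evaluates the
#' index under the induced-only baseline and the induced+biologic condition
#' and derives the reduction rate and difference. Below-range inputs
#' propagate: the record's `status` becomes `"censored"` and both change
#' quantities are `NA`.
#'
#' @param ds A [cohort_dataset()].
#' @param indices Character vector of index strings; default
#'   [default_indices()].
#' @param ratio_values Optional table of externally supplied ratio-index
#'   values (columns `patient_id`, `condition_kind`, `biologic`, `index`,
#'   `printed_value`). For any ratio index present in this table its values
#'   replace the raw-analyte recomputation, and a course without a cell is
#'   censored. Defaults to the `ratio_values` attribute that
#'   [load_paper_fixture()] attaches; `NULL` for plain recomputation.
#' @param lloq Optional named per-analyte vector of lower limits of
#'   quantification. When given, below-range readings are substituted by
#'   `lloq/2` instead of censoring (off by default; the published analysis
#'   leaves censored cells empty).
#' @return Tibble with one row per course x index: `patient_id`, `biologic`,
#'   `index`, `baseline`, `treated`, `reduction_rate`, `difference`, `status`.
#'   Indices referencing analytes that the dataset never measured are dropped
#'   and listed in the `dropped_indices` attribute.
#' @export
build_index_change_table <- function(ds, indices = default_indices(),
                                     ratio_values = attr(ds, "ratio_values"),
                                     lloq = NULL) {
  stopifnot(inherits(ds, "pso_cohort"))
  if (length(indices) == 0) {
    return(tibble::tibble(
      patient_id = character(), biologic = character(), index = character(),
      baseline = numeric(), treated = numeric(),
      reduction_rate = numeric(), difference = numeric(), status = character()
    ))
  }
  parsed <- lapply(indices, parse_index)
  labels <- vapply(parsed, `[[`, character(1), "label")
  overridden <- if (!is.null(ratio_values)) unique(ratio_values$index) else character()

  # indices referencing analytes never measured in this dataset cannot be
  # evaluated on any course; drop them and record which (the packaged cohort
  # has no IL-17A or IL-6 measurements, for instance)
  measured <- unique(ds$assays$analyte)
  evaluable <- vapply(parsed, function(idx) {
    idx$label %in% overridden ||
      all(c(idx$numerator, idx$denominator[!is.na(idx$denominator)]) %in% measured)
  }, logical(1))
  dropped <- labels[!evaluable]
  parsed <- parsed[evaluable]
  labels <- labels[evaluable]

  a <- ds$assays
  if (!is.null(lloq)) {
    # LLOQ/2 substitution for censored readings
    sub <- a$censor == "below_range" & a$analyte %in% names(lloq)
    a$concentration_pg_ml[sub] <- lloq[a$analyte[sub]] / 2
    a$censor[sub] <- "observed"
  }

  panel_of <- function(pid, kind, bio) {
    if (kind == "induced") {
      a[a$patient_id == pid & a$condition_kind == "induced", ]
    } else {
      a[a$patient_id == pid & a$condition_kind == kind &
          !is.na(a$biologic) & a$biologic == bio, ]
    }
  }
  lookup_override <- function(pid, kind, bio, label) {
    rv <- ratio_values[ratio_values$patient_id == pid &
                         ratio_values$condition_kind == kind &
                         ratio_values$index == label, ]
    if (kind == "induced_plus_biologic") {
      rv <- rv[!is.na(rv$biologic) & rv$biologic == bio, ]
    }
    if (nrow(rv) == 0 || is.na(rv$printed_value[1])) {
      list(value = NA_real_, status = "censored")
    } else {
      list(value = rv$printed_value[1], status = "complete")
    }
  }

  co <- ds$courses
  rows <- vector("list", nrow(co) * length(parsed))
  k <- 0L
  for (i in seq_len(nrow(co))) {
    pid <- co$patient_id[i]; bio <- co$biologic[i]
    base_panel <- panel_of(pid, "induced", NULL)
    if (nrow(base_panel) == 0) {
      stop(sprintf("patient %s has no induced-only panel", pid), call. = FALSE)
    }
    trt_panel <- panel_of(pid, "induced_plus_biologic", bio)
    if (nrow(trt_panel) == 0) {
      stop(sprintf("course %s/%s has no induced+biologic panel", pid, bio),
           call. = FALSE)
    }
    for (j in seq_along(parsed)) {
      idx <- parsed[[j]]
      if (idx$label %in% overridden) {
        b <- lookup_override(pid, "induced", NULL, idx$label)
        t <- lookup_override(pid, "induced_plus_biologic", bio, idx$label)
      } else {
        b <- compute_index_value(base_panel, idx)
        t <- compute_index_value(trt_panel, idx)
      }
      censored <- b$status == "censored" || t$status == "censored"
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        patient_id = pid, biologic = bio, index = idx$label,
        baseline = b$value, treated = t$value,
        reduction_rate = if (censored) NA_real_ else reduction_rate(b$value, t$value),
        difference = if (censored) NA_real_ else reduction_difference(b$value, t$value),
        status = if (censored) "censored" else "complete"
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped_indices") <- dropped
  out
}
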