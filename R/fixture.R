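#' Load the packaged 20-patient study cohort
#'
#' Returns the transcription of the published cohort: 20 psoriasis patients
#' (10 PsO-only, 10 PsO+PsA), 44 patient-biologic course rows with absolute
#' PASI before/after, and per-patient IFN-g, IL-13 and IL-4 panels under the
#' S. pyogenes-induced condition and each induced+biologic condition. Patient
#' A's IL-4 under ustekinumab was below the assay range and is carried as a
#' censored measurement.
#'
#' The source table prints the IFN-g/IL-13 and IFN-g/IL-4 ratio columns
#' alongside the raw analytes, and in 22 of 125 cells the two disagree (the
#' ratio columns were evidently computed from unrounded source data, the raw
#' columns hand-rounded, and each carries a few independent misprints). The
#' published correlation analysis follows the ratio columns for ratio
#' biomarkers and the raw columns for single analytes, so with
#' `ratio_source = "printed"` (default) the returned cohort carries the
#' printed ratio cells and [build_index_change_table()] uses them for the two
#' ratio indices they cover. Two print-stage defects are repaired on load:
#' patient S's after-treatment ratio cells are swapped back between its
#' ustekinumab and ixekizumab rows (each printed cell matches the raw
#' recomputation of the other row), and patient A's blank IFN-g/IL-4 cells
#' (IL-4 at the assay floor, 0.09 pg/mL) are carried as censored. With
#' `ratio_source = "recomputed"` ratio indices are instead recomputed from the
#' raw analyte columns.
#'
#' @param ratio_source `"printed"` (default) or `"recomputed"`; see Details.
#' @return A [cohort_dataset()]; with `ratio_source = "printed"` it carries a
#'   `ratio_values` attribute consumed by [build_index_change_table()].
#' @export
#' @examples
#' ds <- load_paper_fixture()
#' nrow(ds$patients)
#' nrow(ds$courses)
load_paper_fixture <- function(ratio_source = c("printed", "recomputed")) {
  ratio_source <- match.arg(ratio_source)
  ext <- function(f) system.file("extdata", f, package = "psoscreen", mustWork = TRUE)
  ds <- read_cohort_csv(ext("patients.csv"), ext("courses.csv"), ext("assays.csv"))

  printed <- utils::read.csv(ext("table2_printed_ratios.csv"),
                             stringsAsFactors = FALSE, na.strings = "")
  printed$biologic[is.na(printed$biologic)] <- NA_character_

  # print-stage repair: patient S's after-treatment ratio cells are swapped
  # between the ust and ixe rows
  for (idx in c("IFN-g/IL-13", "IFN-g/IL-4")) {
    i_ust <- which(printed$patient_id == "S" & !is.na(printed$biologic) &
                     printed$biologic == "ust" & printed$index == idx)
    i_ixe <- which(printed$patient_id == "S" & !is.na(printed$biologic) &
                     printed$biologic == "ixe" & printed$index == idx)
    tmp <- printed$printed_value[i_ust]
    printed$printed_value[i_ust] <- printed$printed_value[i_ixe]
    printed$printed_value[i_ixe] <- tmp
  }

  if (ratio_source == "printed") {
    attr(ds, "ratio_values") <- tibble::as_tibble(printed)
  }
  attr(ds, "table1_relative_pasi") <-
    tibble::as_tibble(utils::read.csv(ext("table1_relative_pasi.csv"),
                                      stringsAsFactors = FALSE))
  ds
}

#' The printed ratio columns of the source table, as transcribed
#'
#' Exact transcription of the IFN-g/IL-13 and IFN-g/IL-4 columns (no repair
#' of the patient-S row swap), for integrity checks against the raw analytes.
#'
#' @return Tibble with columns `patient_id`, `condition_kind`, `biologic`,
#'   `index`, `printed_value`.
#' @export
fixture_printed_ratios <- function() {
  ext <- system.file("extdata", "table2_printed_ratios.csv",
                     package = "psoscreen", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(ext, stringsAsFactors = FALSE, na.strings = ""))
}
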