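#' Orientation of a biomarker index for selection scoring
#'
#' The prescreening principle: a favourable biologic lowers the Th1/Th17
#' markers (IFN-g, IL-17A) and the Th1/Th17-over-Th2 ratios, and raises the
#' Th2 markers (IL-13, IL-4). Indices where lower is better enter the
#' composite with sign +1; IL-13 and IL-4 enter with sign -1.
#'
#' @param index Index label(s).
#' @return Numeric vector of +1/-1.
#' @export
index_orientation <- function(index) {
  ifelse(index %in% c("IL-13", "IL-4", "IL-5"), -1, 1)
}

#' Composite selection scores for one patient's biologic panels
#'
#' For each index, the per-biologic reduction rates are standardised within
#' the patient (divided by their standard deviation across that patient's
#' biologics; if the standard deviation is zero the raw rate is used),
#' oriented by [index_orientation()], and averaged over the indices available
#' for that biologic. Lower composite = more favourable ex vivo profile. This
#' composite is this package's own operationalisation of the published
#' direction-of-change selection principle, which states no formula.
#'
#' @param patient_changes An index change table
#'   ([build_index_change_table()]) restricted to ONE patient.
#' @return Tibble per biologic: `biologic`, `composite_score`,
#'   `n_indices_used`, `omitted` (comma-separated censored indices).
#' @export
score_biologics <- function(patient_changes) {
  stopifnot(length(unique(patient_changes$patient_id)) == 1)
  ch <- patient_changes
  # within-patient scale per index
  ch <- dplyr::group_by(ch, index)
  ch <- dplyr::mutate(ch, .sd = stats::sd(reduction_rate[status == "complete"]))
  ch <- dplyr::ungroup(ch)
  scale_ok <- !is.na(ch$.sd) & ch$.sd > 0
  std <- ifelse(scale_ok, ch$reduction_rate / ch$.sd, ch$reduction_rate)
  oriented <- index_orientation(ch$index) * std
  ch$oriented <- ifelse(ch$status == "complete", oriented, NA_real_)
  out <- dplyr::summarise(
    dplyr::group_by(ch, biologic),
    composite_score = mean(oriented[status == "complete"]),
    n_indices_used = sum(status == "complete"),
    omitted = paste(index[status != "complete"], collapse = ","),
    .groups = "drop"
  )
  if (any(out$n_indices_used == 0)) {
    stop(sprintf("all indices censored for biologic(s): %s",
                 paste(out$biologic[out$n_indices_used == 0], collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Rank a patient's candidate biologics from their ex vivo panels
#'
#' Applies [score_biologics()] to the patient's tested biologic panels and
#' ranks them by composite score, ascending (most favourable first); ties are
#' broken alphabetically by biologic label, so the ranking is deterministic
#' and independent of input order.
#'
#' @param ds A [cohort_dataset()].
#' @param patient_id Patient identifier; must have at least 2 tested
#'   biologic panels.
#' @param indices Indices entering the composite; default the available
#'   subset of [headline_indices()].
#' @return A `pso_selection`: list with `patient_id`, `ranking` (tibble,
#'   sorted), `per_index_changes`, `recommended` (first-ranked biologic).
#' @export
rank_biologics <- function(ds, patient_id, indices = headline_indices()) {
  stopifnot(inherits(ds, "pso_cohort"))
  if (!patient_id %in% ds$patients$patient_id) {
    stop(sprintf("unknown patient %s", shQuote(patient_id)), call. = FALSE)
  }
  panels <- unique(ds$assays$biologic[
    ds$assays$patient_id == patient_id &
      ds$assays$condition_kind == "induced_plus_biologic"
  ])
  panels <- panels[!is.na(panels)]
  if (length(panels) < 2) {
    stop(sprintf("patient %s has %d biologic panel(s); ranking needs at least 2",
                 patient_id, length(panels)), call. = FALSE)
  }
  sub <- cohort_dataset(
    ds$patients[ds$patients$patient_id == patient_id, ],
    # synthesise one course row per tested panel so panels without a clinical
    # course (prescreening use) are still scored
    tibble::tibble(
      patient_id = patient_id, biologic = sort(panels),
      order_index = seq_along(panels), pasi_before = 1, pasi_after = 1,
      months_to_outcome = 1, tested_before_start = TRUE
    ),
    ds$assays[ds$assays$patient_id == patient_id, ],
    validate = FALSE
  )
  attr(sub, "ratio_values") <- attr(ds, "ratio_values")
  changes <- build_index_change_table(sub, indices)
  scores <- score_biologics(changes)
  ord <- order(scores$composite_score, scores$biologic)
  ranking <- scores[ord, ]
  structure(
    list(patient_id = patient_id, ranking = ranking,
         per_index_changes = changes[order(changes$biologic, changes$index),
                                     c("patient_id", "biologic", "index",
                                       "reduction_rate", "difference", "status")],
         recommended = ranking$biologic[1]),
    class = "pso_selection"
  )
}

#' @export
print.pso_selection <- function(x, ...) {
  cat(sprintf("<pso_selection> patient %s — recommended: %s\n",
              x$patient_id, x$recommended))
  df <- as.data.frame(x$ranking)
  df$composite_score <- round(df$composite_score, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a selection report as JSON
#'
#' @param report A [rank_biologics()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
selection_to_json <- function(report, path) {
  jsonlite::write_json(
    list(patient_id = report$patient_id, recommended = report$recommended,
         ranking = report$ranking, per_index_changes = report$per_index_changes),
    path, dataframe = "rows", na = "null", digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
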