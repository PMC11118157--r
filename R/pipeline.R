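#' Published reference correlations (PASI row)
#'
#' The published Spearman correlations between clinical PASI change and each
#' biomarker change, overall and in the PsO-only / PsO+PsA strata, as printed
#' — the reference that [reproduce_paper()] diffs against.
#'
#' @return Tibble: `scope` (`overall`, `PsO-only`, `PsO+PsA`), `mode`,
#'   `variable`, `rho_printed`.
#' @export
paper_reference_correlations <- function() {
  tribble <- tibble::tribble
  tribble(
    ~scope, ~mode, ~variable, ~rho_printed,
    "overall", "rate", "IFN-g", 0.22,
    "overall", "rate", "IL-13", -0.48,
    "overall", "rate", "IL-4", -0.05,
    "overall", "rate", "IFN-g/IL-13", 0.52,
    "overall", "rate", "IFN-g/IL-4", 0.29,
    "overall", "difference", "IFN-g", 0.45,
    "overall", "difference", "IL-13", -0.14,
    "overall", "difference", "IL-4", 0.13,
    "overall", "difference", "IFN-g/IL-13", 0.41,
    "overall", "difference", "IFN-g/IL-4", 0.32,
    "PsO-only", "rate", "IFN-g", 0.02,
    "PsO-only", "rate", "IL-13", -0.35,
    "PsO-only", "rate", "IL-4", 0.27,
    "PsO-only", "rate", "IFN-g/IL-13", 0.30,
    "PsO-only", "rate", "IFN-g/IL-4", -0.26,
    "PsO-only", "difference", "IFN-g", 0.46,
    "PsO-only", "difference", "IL-13", -0.40,
    "PsO-only", "difference", "IL-4", 0.10,
    "PsO-only", "difference", "IFN-g/IL-13", 0.63,
    "PsO-only", "difference", "IFN-g/IL-4", 0.23,
    "PsO+PsA", "rate", "IFN-g", 0.35,
    "PsO+PsA", "rate", "IL-13", -0.46,
    "PsO+PsA", "rate", "IL-4", -0.31,
    "PsO+PsA", "rate", "IFN-g/IL-13", 0.56,
    "PsO+PsA", "rate", "IFN-g/IL-4", 0.50,
    "PsO+PsA", "difference", "IFN-g", 0.53,
    "PsO+PsA", "difference", "IL-13", -0.03,
    "PsO+PsA", "difference", "IL-4", 0.11,
    "PsO+PsA", "difference", "IFN-g/IL-13", 0.35,
    "PsO+PsA", "difference", "IFN-g/IL-4", 0.38
  )
}

#' Recompute the published correlation tables from the packaged cohort
#'
#' Runs the full pipeline on [load_paper_fixture()] — change tables, overall
#' and PsO/PsA-stratified correlation matrices — and diffs every PASI-row
#' cell against [paper_reference_correlations()].
#'
#' @param tolerance Allowed absolute deviation from the printed rho (default
#'   0.03, the slack implied by the source table's 2-dp rounding).
#' @return Tibble: scope, mode, variable, `rho_printed`, `rho_computed`, `n`,
#'   `deviation`, `within_tolerance`.
#' @export
#' @examples
#' \donttest{
#' rep <- reproduce_paper()
#' subset(rep, !within_tolerance)
#' }
reproduce_paper <- function(tolerance = 0.03) {
  ds <- load_paper_fixture()
  changes <- analysis_change_table(ds)
  mats <- list(
    "overall.rate" = correlation_matrix(changes, "rate"),
    "overall.difference" = correlation_matrix(changes, "difference")
  )
  mats <- c(mats, subgroup_analyses(changes, ds, "by_disease"))
  ref <- paper_reference_correlations()
  ref$rho_computed <- NA_real_; ref$n <- NA_integer_
  for (i in seq_len(nrow(ref))) {
    mat <- mats[[paste(ref$scope[i], ref$mode[i], sep = ".")]]
    cell <- cormat_cell(mat, "PASI", ref$variable[i])
    ref$rho_computed[i] <- cell$rho
    ref$n[i] <- cell$n
  }
  ref$deviation <- abs(ref$rho_computed - ref$rho_printed)
  ref$within_tolerance <- !is.na(ref$deviation) & ref$deviation <= tolerance
  ref
}

#' Configure a pipeline run
#'
#' @param input `"fixture"`, `"csv"`, or `"simulate"`.
#' @param csv_paths For `input = "csv"`: named list/vector with `patients`,
#'   `courses`, `assays` paths.
#' @param sim_config For `input = "simulate"`: a [simulation_config()]
#'   (default one is used if omitted).
#' @param indices Index strings (default [default_indices()]).
#' @param modes Subset of `c("rate", "difference")`; at least one.
#' @param subgroups Subset of `c("none", "by_biologic", "by_disease")`.
#' @param output_dir Where the report bundle is written.
#' @param thresholds Strictly decreasing significance-star cutoffs.
#' @param bh_correct Benjamini-Hochberg adjusted p-values alongside raw ones.
#' @param seed Optional integer; overrides the simulation config's seed.
#' @return A validated list with class `"pso_runconfig"`.
#' @export
run_config <- function(input = c("fixture", "csv", "simulate"),
                       csv_paths = NULL, sim_config = NULL,
                       indices = default_indices(),
                       modes = c("rate", "difference"),
                       subgroups = "by_disease",
                       output_dir = tempfile("psoscreen-run-"),
                       thresholds = c(0.05, 0.01, 0.001),
                       bh_correct = FALSE, seed = NULL) {
  input <- match.arg(input)
  modes <- match.arg(modes, c("rate", "difference"), several.ok = TRUE)
  subgroups <- match.arg(subgroups, c("none", "by_biologic", "by_disease"),
                         several.ok = TRUE)
  if (length(modes) < 1) stop("select at least one mode", call. = FALSE)
  if (length(thresholds) != 3 || any(diff(thresholds) >= 0)) {
    stop("significance thresholds must be three strictly decreasing values",
         call. = FALSE)
  }
  if (input == "csv") {
    stopifnot(!is.null(csv_paths),
              all(c("patients", "courses", "assays") %in% names(csv_paths)))
  }
  if (input == "simulate") {
    if (is.null(sim_config)) sim_config <- simulation_config()
    if (!is.null(seed)) {
      sim_config$seed <- as.integer(seed)
    }
  }
  structure(
    list(input = input, csv_paths = csv_paths, sim_config = sim_config,
         indices = indices, modes = modes, subgroups = subgroups,
         output_dir = output_dir, thresholds = thresholds,
         bh_correct = bh_correct, seed = seed),
    class = "pso_runconfig"
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Loads or simulates a cohort, builds the PASI and biomarker change tables,
#' computes the requested correlation matrices (overall and per subgroup),
#' ranks each multi-panel patient's biologics, and writes the report bundle
#' to `cfg$output_dir`: `change_table.csv`, `pasi_change.csv`, one
#' `cormat_*.csv` per matrix (long format with n/rho/p/stars), one
#' `selection_*.json` per eligible patient, and `manifest.json` (config,
#' package version, dropped indices). Outputs are deterministic given the
#' config; re-running reproduces identical files.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the cohort, change table, matrices and
#'   selection reports.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pso_runconfig"))
  ds <- switch(cfg$input,
    fixture = load_paper_fixture(),
    csv = read_cohort_csv(cfg$csv_paths[["patients"]], cfg$csv_paths[["courses"]],
                          cfg$csv_paths[["assays"]]),
    simulate = simulate_cohort(cfg$sim_config)
  )
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)

  idx_changes <- build_index_change_table(ds, cfg$indices)
  pasi <- pasi_change_table(ds)
  changes <- analysis_change_table(ds, cfg$indices)
  utils::write.csv(idx_changes, out("change_table.csv"), row.names = FALSE, na = "")
  utils::write.csv(pasi, out("pasi_change.csv"), row.names = FALSE, na = "")

  mats <- list()
  for (m in cfg$modes) {
    mats[[paste0("overall.", m)]] <- correlation_matrix(
      changes, m, thresholds = cfg$thresholds, bh_correct = cfg$bh_correct)
  }
  for (g in setdiff(cfg$subgroups, "none")) {
    mats <- c(mats, subgroup_analyses(changes, ds, g, modes = cfg$modes,
                                      thresholds = cfg$thresholds,
                                      bh_correct = cfg$bh_correct))
  }
  for (nm in names(mats)) {
    fn <- paste0("cormat_", gsub("[^A-Za-z0-9._-]", "_", nm), ".csv")
    utils::write.csv(mats[[nm]]$cells, out(fn), row.names = FALSE, na = "")
  }

  eligible <- ds$assays[ds$assays$condition_kind == "induced_plus_biologic", ]
  n_panels <- tapply(eligible$biologic, eligible$patient_id,
                     function(b) length(unique(b)))
  selections <- list()
  for (pid in names(n_panels)[n_panels >= 2]) {
    sel <- rank_biologics(ds, pid, intersect(headline_indices(), cfg$indices))
    selections[[pid]] <- sel
    selection_to_json(sel, out(paste0("selection_", pid, ".json")))
  }

  manifest <- list(
    package = "psoscreen",
    version = as.character(utils::packageVersion("psoscreen")),
    input = cfg$input,
    indices = cfg$indices,
    dropped_indices = attr(idx_changes, "dropped_indices"),
    modes = cfg$modes, subgroups = cfg$subgroups,
    thresholds = cfg$thresholds, bh_correct = cfg$bh_correct,
    seed = if (cfg$input == "simulate") cfg$sim_config$seed else cfg$seed,
    n_patients = nrow(ds$patients), n_courses = nrow(ds$courses),
    outputs = list.files(cfg$output_dir)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = ds, changes = changes, matrices = mats,
                 selections = selections, manifest = manifest))
}
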