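#' Assemble a cohort dataset
#'
#' A cohort bundles three tables: one row per patient (`patients`), one row
#' per patient-biologic treatment course with absolute PASI before/after
#' (`courses`), and one row per assay measurement (`assays`) — an analyte
#' concentration in pg/mL for one patient under one culture condition, with a
#' censor flag (`"observed"` or `"below_range"` for readings below the assay's
#' detection range).
#'
#' The unit of analysis throughout the package is the patient-biologic course
#' row, not the patient: a patient contributes one course per biologic tested.
#'
#' @param patients Data frame with columns `patient_id`, `age`, `sex`,
#'   `pso`, `psa`, `comorbidities`.
#' @param courses Data frame with columns `patient_id`, `biologic`,
#'   `order_index`, `pasi_before`, `pasi_after`, `months_to_outcome`,
#'   `tested_before_start`.
#' @param assays Data frame with columns `patient_id`, `condition_kind`,
#'   `biologic`, `dose_ug_ml`, `analyte`, `concentration_pg_ml`, `censor`.
#' @param validate Stop on invariant violations? Default `TRUE`.
#' @return An object of class `"pso_cohort"`.
#' @seealso [validate_cohort()], [read_cohort_csv()], [load_paper_fixture()]
#' @export
cohort_dataset <- function(patients, courses, assays, validate = TRUE) {
  patients <- tibble::as_tibble(patients)
  courses <- tibble::as_tibble(courses)
  assays <- tibble::as_tibble(assays)
  # canonical column types, so write -> read round trips are exact
  patients$patient_id <- as.character(patients$patient_id)
  patients$age <- as.numeric(patients$age)
  patients$sex <- as.character(patients$sex)
  patients$pso <- as.logical(patients$pso)
  patients$psa <- as.logical(patients$psa)
  patients$comorbidities <- as.character(patients$comorbidities)
  patients$comorbidities[is.na(patients$comorbidities)] <- ""
  courses$patient_id <- as.character(courses$patient_id)
  courses$biologic <- as.character(courses$biologic)
  courses$order_index <- as.integer(courses$order_index)
  for (f in c("pasi_before", "pasi_after", "months_to_outcome")) {
    courses[[f]] <- as.numeric(courses[[f]])
  }
  courses$tested_before_start <- as.logical(courses$tested_before_start)
  assays$patient_id <- as.character(assays$patient_id)
  assays$condition_kind <- as.character(assays$condition_kind)
  assays$biologic <- as.character(assays$biologic)
  assays$dose_ug_ml <- as.numeric(assays$dose_ug_ml)
  assays$concentration_pg_ml <- as.numeric(assays$concentration_pg_ml)
  assays$censor <- as.character(assays$censor)
  assays$analyte <- normalize_analyte(assays$analyte)
  ds <- structure(list(patients = patients, courses = courses, assays = assays),
                  class = "pso_cohort")
  if (validate) {
    issues <- validate_cohort(ds)
    if (length(issues)) {
      stop(paste(c("invalid cohort dataset:", issues), collapse = "\n  "),
           call. = FALSE)
    }
  }
  ds
}

#' Validate a cohort dataset against its invariants
#'
#' Checks referential integrity (every course and assay references a known
#' patient), key uniqueness, the PASI scale bound (0-72), censor-flag
#' consistency (a `below_range` measurement carries no concentration),
#' biologic trough doses, and that every patient with assay data has exactly
#' one induced-only panel.
#'
#' @param ds A [cohort_dataset()].
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_cohort <- function(ds) {
  p <- ds$patients; co <- ds$courses; a <- ds$assays
  out <- character()
  say <- function(...) out[[length(out) + 1]] <<- sprintf(...)

  if (anyDuplicated(p$patient_id)) {
    say("duplicate patient_id in patients: %s",
        paste(unique(p$patient_id[duplicated(p$patient_id)]), collapse = ", "))
  }
  if (any(!p$pso)) {
    say("patients without psoriasis violate the inclusion criterion: %s",
        paste(p$patient_id[!p$pso], collapse = ", "))
  }

  dangling <- setdiff(co$patient_id, p$patient_id)
  if (length(dangling)) say("courses reference unknown patients: %s",
                            paste(dangling, collapse = ", "))
  dangling <- setdiff(a$patient_id, p$patient_id)
  if (length(dangling)) say("assays reference unknown patients: %s",
                            paste(dangling, collapse = ", "))

  key <- paste(co$patient_id, co$biologic)
  if (anyDuplicated(key)) say("duplicate (patient, biologic) course rows: %s",
                              paste(unique(key[duplicated(key)]), collapse = ", "))

  bad <- co$pasi_before < 0 | co$pasi_before > 72 |
    co$pasi_after < 0 | co$pasi_after > 72
  if (any(bad)) {
    say("PASI outside the 0-72 scale bound for course(s): %s",
        paste(key[bad], collapse = ", "))
  }
  if (any(co$months_to_outcome <= 0)) {
    say("months_to_outcome must be positive for course(s): %s",
        paste(key[co$months_to_outcome <= 0], collapse = ", "))
  }
  if (any(!co$biologic %in% biologic_names())) {
    say("unknown biologic label(s) in courses: %s",
        paste(setdiff(co$biologic, biologic_names()), collapse = ", "))
  }

  akey <- paste(a$patient_id, a$condition_kind,
                ifelse(is.na(a$biologic), "", a$biologic), a$analyte)
  if (anyDuplicated(akey)) {
    say("duplicate (patient, condition, analyte) assay rows: %s",
        paste(unique(akey[duplicated(akey)]), collapse = ", "))
  }
  if (any(!a$censor %in% c("observed", "below_range"))) {
    say("censor must be 'observed' or 'below_range'")
  }
  cen <- a$censor == "below_range"
  if (any(cen & !is.na(a$concentration_pg_ml))) {
    say("below_range measurements must have no concentration: %s",
        paste(akey[cen & !is.na(a$concentration_pg_ml)], collapse = ", "))
  }
  if (any(!cen & (is.na(a$concentration_pg_ml) | a$concentration_pg_ml < 0))) {
    say("observed measurements need a non-negative concentration: %s",
        paste(akey[!cen & (is.na(a$concentration_pg_ml) | a$concentration_pg_ml < 0)],
              collapse = ", "))
  }

  trt <- a$condition_kind == "induced_plus_biologic"
  if (any(trt & is.na(a$biologic))) say("induced_plus_biologic assay rows need a biologic")
  if (any(!trt & !is.na(a$biologic))) {
    say("control/induced assay rows must not carry a biologic")
  }
  troughs <- biologic_troughs()
  for (i in which(trt & !is.na(a$biologic))) {
    b <- a$biologic[i]
    if (!b %in% names(troughs)) { say("unknown biologic %s in assays", shQuote(b)); next }
    if (!is.na(a$dose_ug_ml[i]) && !any(abs(a$dose_ug_ml[i] - troughs[[b]]) < 1e-9)) {
      say("assay dose %g ug/mL is not the trough for %s (row %s)",
          a$dose_ug_ml[i], b, akey[i])
    }
  }

  for (pid in unique(a$patient_id)) {
    k <- a$condition_kind[a$patient_id == pid]
    if (!any(k == "induced")) say("patient %s has assay data but no induced-only panel", pid)
  }
  out
}

#' @export
print.pso_cohort <- function(x, ...) {
  cat(sprintf(
    "<pso_cohort> %d patients, %d biologic courses, %d assay measurements (%d censored)\n",
    nrow(x$patients), nrow(x$courses), nrow(x$assays),
    sum(x$assays$censor == "below_range")
  ))
  if (!is.null(attr(x, "ratio_values"))) {
    cat("  carries printed ratio-column values for ratio indices\n")
  }
  invisible(x)
}

.course_cols <- c("patient_id", "biologic", "order_index", "pasi_before",
                  "pasi_after", "months_to_outcome", "tested_before_start")
.patient_cols <- c("patient_id", "age", "sex", "pso", "psa", "comorbidities")
.assay_cols <- c("patient_id", "condition_kind", "biologic", "dose_ug_ml",
                 "analyte", "concentration_pg_ml", "censor")

read_checked_csv <- function(path, cols, col_classes) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    colClasses = col_classes, na.strings = ""),
    error = function(e) stop(sprintf("parse error in %s: %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[cols]
}

#' Read a cohort from the three-file CSV dialect
#'
#' The dialect is UTF-8, comma-separated, header row mandatory, decimal point
#' `.`, empty string for an absent value. `patients.csv` holds demographics
#' and PsO/PsA flags, `courses.csv` one row per patient-biologic course with
#' absolute PASI before/after, `assays.csv` one row per analyte measurement.
#'
#' @param patients_file,courses_file,assays_file Paths to the three CSVs.
#' @return A validated [cohort_dataset()]. Malformed rows and invariant
#'   violations raise errors naming the offending file and field.
#' @export
read_cohort_csv <- function(patients_file, courses_file, assays_file) {
  patients <- read_checked_csv(
    patients_file, .patient_cols,
    c(patient_id = "character", age = "numeric", sex = "character",
      pso = "logical", psa = "logical", comorbidities = "character")
  )
  patients$comorbidities[is.na(patients$comorbidities)] <- ""
  if (any(!patients$sex %in% c("M", "F"))) {
    stop(sprintf("%s: field 'sex' must be M or F (rows %s)", patients_file,
                 paste(which(!patients$sex %in% c("M", "F")) + 1, collapse = ", ")),
         call. = FALSE)
  }
  courses <- read_checked_csv(
    courses_file, .course_cols,
    c(patient_id = "character", biologic = "character", order_index = "integer",
      pasi_before = "numeric", pasi_after = "numeric",
      months_to_outcome = "numeric", tested_before_start = "logical")
  )
  assays <- read_checked_csv(
    assays_file, .assay_cols,
    c(patient_id = "character", condition_kind = "character",
      biologic = "character", dose_ug_ml = "numeric",
      analyte = "character", concentration_pg_ml = "numeric", censor = "character")
  )
  bad <- which(!assays$condition_kind %in% c("control", "induced", "induced_plus_biologic"))
  if (length(bad)) {
    stop(sprintf("%s: field 'condition_kind' invalid at data row(s) %s",
                 assays_file, paste(bad, collapse = ", ")), call. = FALSE)
  }
  cohort_dataset(patients, courses, assays)
}

#' Write a cohort in the three-file CSV dialect
#'
#' @param ds A [cohort_dataset()].
#' @param dir Output directory (created if needed); files are named
#'   `patients.csv`, `courses.csv`, `assays.csv`.
#' @return Invisibly, the three file paths.
#' @export
write_cohort_csv <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "courses.csv", "assays.csv"))
  utils::write.csv(ds$patients, paths[1], row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  utils::write.csv(ds$courses, paths[2], row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  utils::write.csv(ds$assays, paths[3], row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(paths)
}

#' Export or import a cohort as JSON
#'
#' JSON mirrors the CSV schema: an object with `patients`, `courses` and
#' `assays` arrays.
#'
#' @param ds A [cohort_dataset()].
#' @param path Output (or input) file path.
#' @return `cohort_to_json()` invisibly returns `path`; `cohort_from_json()`
#'   returns a validated [cohort_dataset()].
#' @export
cohort_to_json <- function(ds, path) {
  jsonlite::write_json(
    list(patients = ds$patients, courses = ds$courses, assays = ds$assays),
    path, dataframe = "rows", na = "null", digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname cohort_to_json
#' @export
cohort_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("biologic")) {
    if (is.null(x$assays[[f]])) x$assays[[f]] <- NA_character_
  }
  cohort_dataset(x$patients, x$courses, x$assays)
}
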