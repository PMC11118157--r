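#' The 18-analyte multiplex panel
#'
#' The assay measures 18 cytokines/chemokines per culture supernatant.
#' Canonical labels use ASCII (`IFN-g`, `TNF-a`, `IL-1b`, `MIP-1a`, `MIP-1b`);
#' Greek spellings and a few common variants are accepted on input and
#' normalised with [normalize_analyte()].
#'
#' @return Character vector of the 18 canonical analyte labels.
#' @export
#' @examples
#' analyte_names()
analyte_names <- function() {
  c(
    "IL-1b", "IL-2", "IL-4", "IL-5", "IL-6", "IL-7", "IL-8", "IL-10",
    "IL-12", "IL-13", "IL-17A", "IFN-g", "TNF-a", "MCP-1", "MIP-1a",
    "MIP-1b", "PDGF-BB", "RANTES"
  )
}

# alias -> canonical; lookups are case-insensitive after this map
.analyte_aliases <- c(
  "IFN-γ" = "IFN-g", "IFNG" = "IFN-g", "IFN-GAMMA" = "IFN-g",
  "TNF-α" = "TNF-a", "TNF-ALPHA" = "TNF-a",
  "IL-1β" = "IL-1b", "IL-1BETA" = "IL-1b",
  "MIP-1α" = "MIP-1a", "MIP-1β" = "MIP-1b",
  "IL-17" = "IL-17A", "CCL5" = "RANTES", "CCL2" = "MCP-1"
)

#' Normalise analyte labels to the canonical panel spelling
#'
#' @param x Character vector of analyte labels (canonical, Greek, or common
#'   alias spellings).
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' normalize_analyte(c("IFN-γ", "il-13"))
normalize_analyte <- function(x) {
  up <- toupper(trimws(x))
  hit <- match(up, toupper(names(.analyte_aliases)))
  out <- ifelse(is.na(hit), x, .analyte_aliases[hit])
  canon <- analyte_names()
  idx <- match(toupper(trimws(out)), toupper(canon))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop(sprintf(
      "unknown analyte label(s): %s (panel has 18 analytes, see analyte_names())",
      paste(shQuote(bad), collapse = ", ")
    ), call. = FALSE)
  }
  canon[idx]
}

#' Trough serum concentrations of the assayed biologics
#'
#' Each biologic is added to the induced culture at its steady-state trough
#' serum concentration. Secukinumab has two admissible concentrations,
#' mirroring the 150 mg and 300 mg monthly clinical doses.
#'
#' @return Named list; one numeric vector of admissible doses (ug/mL) per
#'   biologic abbreviation.
#' @export
#' @examples
#' biologic_troughs()$sec
biologic_troughs <- function() {
  list(
    ada = 4, gol = 0.5, cer = 20, ust = 0.25,
    ixe = 3.5, sec = c(16.7, 34), gus = 1.2, ris = 2
  )
}

#' @rdname biologic_troughs
#' @export
biologic_names <- function() names(biologic_troughs())

#' Construct a culture-condition descriptor
#'
#' A panel is measured under one of three conditions: unstimulated `control`,
#' S. pyogenes `induced`, or `induced_plus_biologic` (induced culture plus one
#' biologic at its trough concentration).
#'
#' @param kind One of `"control"`, `"induced"`, `"induced_plus_biologic"`.
#' @param biologic Biologic abbreviation; required iff `kind` is
#'   `"induced_plus_biologic"`.
#' @param dose Concentration in ug/mL; must match the configured trough for
#'   the biologic. Defaults to that trough (first admissible value).
#' @return A list with class `"pso_condition"`.
#' @export
#' @examples
#' condition("induced_plus_biologic", "ada")
condition <- function(kind = c("control", "induced", "induced_plus_biologic"),
                      biologic = NULL, dose = NULL) {
  kind <- match.arg(kind)
  if (kind != "induced_plus_biologic") {
    if (!is.null(biologic) || !is.null(dose)) {
      stop("biologic and dose are only meaningful for kind = 'induced_plus_biologic'",
           call. = FALSE)
    }
    return(structure(list(kind = kind, biologic = NULL, dose = NULL),
                     class = "pso_condition"))
  }
  if (is.null(biologic)) {
    stop("an induced_plus_biologic condition needs a biologic label", call. = FALSE)
  }
  troughs <- biologic_troughs()
  if (!biologic %in% names(troughs)) {
    stop(sprintf("unknown biologic %s; known: %s", shQuote(biologic),
                 paste(names(troughs), collapse = ", ")), call. = FALSE)
  }
  admissible <- troughs[[biologic]]
  if (is.null(dose)) dose <- admissible[1]
  if (!any(abs(dose - admissible) < 1e-9)) {
    stop(sprintf("dose %g ug/mL is not the configured trough for %s (admissible: %s)",
                 dose, biologic, paste(admissible, collapse = " or ")), call. = FALSE)
  }
  structure(list(kind = kind, biologic = biologic, dose = dose),
            class = "pso_condition")
}

#' @export
print.pso_condition <- function(x, ...) {
  if (x$kind == "induced_plus_biologic") {
    cat(sprintf("<condition> S. pyogenes + %s (%g ug/mL)\n", x$biologic, x$dose))
  } else {
    cat(sprintf("<condition> %s\n", x$kind))
  }
  invisible(x)
}
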