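#' Spearman rank correlation with midrank ties
#'
#' The Pearson correlation of midranks (ties receive average ranks), the
#' association statistic used throughout the package.
#'
#' @param x,y Equal-length numeric vectors without missing values (perform
#'   pairwise deletion first).
#' @return The rank correlation in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(1:4, c(10, 20, 30, 40))
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values: perform pairwise deletion first",
                                 call. = FALSE)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    stop("rank correlation is undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

# all permutations of 1:n as an n! x n matrix, memoised (used for the exact
# permutation null of the rank correlation)
.perm_cache <- new.env(parent = emptyenv())
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- if (n == 1) matrix(1L) else {
    prev <- all_permutations(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, prev + (prev >= i))
    }))
  }
  storage.mode(p) <- "integer"
  if (n <= 9) .perm_cache[[key]] <- p
  p
}

#' Two-sided p-value for a Spearman correlation
#'
#' For n > 9 (or `method = "t_approx"`), the Student-t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom —
#' the convention of mainstream statistical packages, which reproduces the
#' published p-values at n = 44. For n <= 9 the exact permutation null of the
#' rank correlation (all `n!` rank orderings) is enumerated.
#'
#' @param rho Observed rank correlation.
#' @param n Number of paired observations (>= 3).
#' @param method `"auto"` (default), `"t_approx"`, or `"exact_permutation"`.
#' @return Two-sided p-value in (0, 1]. `|rho| = 1` under the t branch
#'   returns the smallest representable positive double, flagged with a
#'   `degenerate` attribute.
#' @export
#' @examples
#' spearman_p(0.22, 44)  # ~0.152
spearman_p <- function(rho, n, method = c("auto", "t_approx", "exact_permutation")) {
  method <- match.arg(method)
  stopifnot(is.numeric(rho), length(rho) == 1, n >= 3, abs(rho) <= 1 + 1e-12)
  if (method == "auto") method <- if (n <= 9) "exact_permutation" else "t_approx"
  if (method == "exact_permutation") {
    perms <- all_permutations(n)
    d2 <- rowSums((perms - matrix(seq_len(n), nrow(perms), n, byrow = TRUE))^2)
    rho_null <- 1 - 6 * d2 / (n * (n^2 - 1))
    return(mean(abs(rho_null) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Spearman correlation test on two vectors with pairwise deletion
#'
#' @param x,y Numeric vectors (may contain `NA`; pairs with any missing value
#'   are dropped).
#' @param var_a,var_b Labels for the result row.
#' @return One-row tibble: `var_a`, `var_b`, `n`, `rho`, `p_value`, `method`.
#'   `rho` and `p_value` are `NA` when fewer than 3 complete pairs remain or
#'   a vector is constant after deletion.
#' @export
spearman_test <- function(x, y, var_a = "x", var_b = "y") {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  res <- tibble::tibble(var_a = var_a, var_b = var_b, n = n,
                        rho = NA_real_, p_value = NA_real_, method = NA_character_)
  if (n < 3) return(res)
  rho <- tryCatch(spearman_rho(x[ok], y[ok]), error = function(e) NA_real_)
  if (is.na(rho)) return(res)
  res$rho <- rho
  res$method <- if (n <= 9) "exact_permutation" else "t_approx"
  res$p_value <- as.numeric(spearman_p(rho, n, res$method))
  res
}

#' Mann-Whitney U test with midrank ties
#'
#' The U statistic for the first group (midranks for ties). The two-sided
#' p-value is exact — enumeration over all assignments of the pooled sample —
#' when `n_a * n_b <= 20`, and otherwise uses the normal approximation with
#' the tie-corrected variance, without continuity correction (the convention
#' of mainstream statistical packages).
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `U`, `p_value`, `method` (`"exact_enumeration"` or
#'   `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 20, 30))  # U = 0, p = 0.1
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na * nb <= 20) {
    subsets <- utils::combn(n, na)
    u_null <- apply(subsets, 2, function(s) sum(r[s])) - na * (na + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_null <= U + eps), mean(u_null >= U - eps))
    return(list(U = U, p_value = min(1, p), method = "exact_enumeration"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z <- (U - na * nb / 2) / sqrt(sigma2)
  list(U = U, p_value = 2 * stats::pnorm(-abs(z)), method = "normal_approx")
}

#' Significance stars
#'
#' @param p Numeric vector of p-values.
#' @param thresholds Strictly decreasing cutoffs for `*`, `**`, `***`.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) < 0))
  out <- rep("", length(p))
  out[!is.na(p) & p < thresholds[1]] <- "*"
  out[!is.na(p) & p < thresholds[2]] <- "**"
  out[!is.na(p) & p < thresholds[3]] <- "***"
  out
}

#' Combined PASI + biomarker change table for association analysis
#'
#' One row per course and variable; the clinical PASI change enters as the
#' variable `"PASI"` with the same rate/difference orientation as the
#' biomarker indices, so a positive correlation means the biomarker falls
#' when the skin improves.
#'
#' @param ds A [cohort_dataset()].
#' @param indices Index strings; default [default_indices()].
#' @param ... Passed to [build_index_change_table()].
#' @return Long tibble: `patient_id`, `biologic`, `variable`, `rate`,
#'   `difference`.
#' @export
analysis_change_table <- function(ds, indices = default_indices(), ...) {
  idx <- build_index_change_table(ds, indices, ...)
  pasi <- pasi_change_table(ds)
  dplyr::bind_rows(
    tibble::tibble(patient_id = pasi$patient_id, biologic = pasi$biologic,
                   variable = "PASI", rate = pasi$rate,
                   difference = pasi$difference),
    tibble::tibble(patient_id = idx$patient_id, biologic = idx$biologic,
                   variable = idx$index, rate = idx$reduction_rate,
                   difference = idx$difference)
  )
}

#' Spearman correlation matrix over PASI and biomarker change variables
#'
#' Computes every pairwise rank correlation among the variables of an
#' [analysis_change_table()], in the requested change mode, with pairwise
#' deletion of censored/missing entries per cell. Cells with fewer than
#' `min_n` complete pairs are reported as undefined (`NA`), not as errors.
#'
#' @param changes An [analysis_change_table()].
#' @param mode `"rate"` or `"difference"`.
#' @param subgroup Optional label recorded on the result (the caller filters
#'   `changes` to the subgroup's rows first; see [subgroup_analyses()]).
#' @param min_n Minimum pairwise-complete pairs for a defined cell (default 3).
#' @param bh_correct Add Benjamini-Hochberg adjusted p-values over the
#'   off-diagonal cells (off by default; the published analysis reports
#'   unadjusted p-values).
#' @param thresholds Star cutoffs, see [significance_stars()].
#' @return A `pso_cormat`: list with `cells` (long tibble of unordered pairs
#'   incl. diagonal), `variables`, `mode`, `subgroup`, `n_courses`, `low_n`.
#' @export
correlation_matrix <- function(changes, mode = c("rate", "difference"),
                               subgroup = NULL, min_n = 3, bh_correct = FALSE,
                               thresholds = c(0.05, 0.01, 0.001)) {
  mode <- match.arg(mode)
  stopifnot(all(c("patient_id", "biologic", "variable") %in% names(changes)))
  vars <- unique(changes$variable)
  value <- changes[[if (mode == "rate") "rate" else "difference"]]
  wide <- tidyr::pivot_wider(
    tibble::tibble(patient_id = changes$patient_id, biologic = changes$biologic,
                   variable = changes$variable, value = value),
    names_from = "variable", values_from = "value"
  )
  n_courses <- nrow(wide)
  cells <- list()
  for (i in seq_along(vars)) {
    for (j in seq(i, length(vars))) {
      if (i == j) {
        cells[[length(cells) + 1]] <- tibble::tibble(
          var_a = vars[i], var_b = vars[i], n = sum(is.finite(wide[[vars[i]]])),
          rho = 1, p_value = NA_real_, method = NA_character_
        )
      } else {
        res <- spearman_test(wide[[vars[i]]], wide[[vars[j]]], vars[i], vars[j])
        if (res$n < min_n) { res$rho <- NA_real_; res$p_value <- NA_real_ }
        cells[[length(cells) + 1]] <- res
      }
    }
  }
  cells <- dplyr::bind_rows(cells)
  cells$stars <- significance_stars(cells$p_value, thresholds)
  if (bh_correct) {
    off <- cells$var_a != cells$var_b
    cells$p_adjusted <- NA_real_
    cells$p_adjusted[off] <- stats::p.adjust(cells$p_value[off], method = "BH")
  }
  structure(
    list(cells = cells, variables = vars, mode = mode, subgroup = subgroup,
         n_courses = n_courses, low_n = n_courses < 4),
    class = "pso_cormat"
  )
}

#' @export
print.pso_cormat <- function(x, digits = 2, ...) {
  hdr <- sprintf("<pso_cormat> mode = %s, %d courses", x$mode, x$n_courses)
  if (!is.null(x$subgroup)) hdr <- paste0(hdr, ", subgroup = ", x$subgroup)
  if (x$low_n) hdr <- paste0(hdr, " [low n]")
  cat(hdr, "\n")
  print(round(as.matrix(x), digits))
  invisible(x)
}

#' @export
as.matrix.pso_cormat <- function(x, ...) {
  v <- x$variables
  m <- matrix(NA_real_, length(v), length(v), dimnames = list(v, v))
  for (k in seq_len(nrow(x$cells))) {
    m[x$cells$var_a[k], x$cells$var_b[k]] <- x$cells$rho[k]
    m[x$cells$var_b[k], x$cells$var_a[k]] <- x$cells$rho[k]
  }
  m
}

#' Extract one cell of a correlation matrix
#'
#' @param mat A [correlation_matrix()].
#' @param var_a,var_b Variable labels (order-insensitive).
#' @return One-row tibble (`n`, `rho`, `p_value`, `stars`, ...).
#' @export
cormat_cell <- function(mat, var_a, var_b) {
  c1 <- mat$cells$var_a == var_a & mat$cells$var_b == var_b
  c2 <- mat$cells$var_a == var_b & mat$cells$var_b == var_a
  out <- mat$cells[c1 | c2, ]
  if (nrow(out) == 0) stop(sprintf("no cell (%s, %s) in matrix", var_a, var_b),
                           call. = FALSE)
  out[1, ]
}

#' Per-biologic and PsO/PsA subgroup correlation analyses
#'
#' Splits the course rows by biologic or by disease stratum (PsO-only vs
#' PsO+PsA, from the patients' psoriatic-arthritis flag) and computes a
#' rate-mode and a difference-mode correlation matrix per subgroup. Subgroups
#' with fewer than 4 course rows are flagged `low_n`; their defined cells are
#' still computed.
#'
#' @param changes An [analysis_change_table()].
#' @param ds The [cohort_dataset()] the table came from (supplies the
#'   PsO/PsA flags).
#' @param grouping `"by_biologic"` or `"by_disease"`.
#' @param modes Modes to compute, subset of `c("rate", "difference")`.
#' @param ... Passed to [correlation_matrix()].
#' @return Named list of `pso_cormat` objects, names `<subgroup>.<mode>`.
#' @export
subgroup_analyses <- function(changes, ds,
                              grouping = c("by_biologic", "by_disease"),
                              modes = c("rate", "difference"), ...) {
  grouping <- match.arg(grouping)
  modes <- match.arg(modes, several.ok = TRUE)
  if (grouping == "by_biologic") {
    keys <- changes$biologic
  } else {
    psa <- stats::setNames(ds$patients$psa, ds$patients$patient_id)
    keys <- ifelse(psa[changes$patient_id], "PsO+PsA", "PsO-only")
  }
  out <- list()
  for (g in sort(unique(keys))) {
    sub <- changes[keys == g, ]
    if (nrow(sub) == 0) next
    for (m in modes) {
      out[[paste(g, m, sep = ".")]] <-
        correlation_matrix(sub, mode = m, subgroup = g, ...)
    }
  }
  out
}

#' Plot-ready long table (and heatmap) for a correlation matrix
#'
#' @param mat A [correlation_matrix()].
#' @return Tibble of the off-diagonal unordered pairs: `var_a`, `var_b`, `n`,
#'   `rho`, `p_value`, `stars`.
#' @export
export_heatmap_table <- function(mat) {
  stopifnot(inherits(mat, "pso_cormat"))
  cells <- mat$cells[mat$cells$var_a != mat$cells$var_b, ]
  cells[c("var_a", "var_b", "n", "rho", "p_value", "stars")]
}

#' @rdname export_heatmap_table
#' @param low,mid,high Fill colours for rho = -1, 0, +1.
#' @return `plot_heatmap()` returns a ggplot object mirroring the published
#'   heatmap style: tiles coloured by rho, annotated with significance stars.
#' @export
plot_heatmap <- function(mat, low = "#2166AC", mid = "white", high = "#B2182B") {
  stopifnot(inherits(mat, "pso_cormat"))
  cells <- mat$cells
  flip <- cells[cells$var_a != cells$var_b,
                c("var_b", "var_a", "n", "rho", "p_value", "method", "stars")]
  names(flip)[1:2] <- c("var_a", "var_b")
  full <- dplyr::bind_rows(cells[c("var_a", "var_b", "rho", "stars")],
                           flip[c("var_a", "var_b", "rho", "stars")])
  full$var_a <- factor(full$var_a, levels = mat$variables)
  full$var_b <- factor(full$var_b, levels = rev(mat$variables))
  full$label <- ifelse(is.na(full$rho), "",
                       paste0(sprintf("%.2f", full$rho), full$stars))
  ggplot2::ggplot(full, ggplot2::aes(x = var_a, y = var_b, fill = rho)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = label), size = 2.8) +
    ggplot2::scale_fill_gradient2(low = low, mid = mid, high = high,
                                  limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "rho",
      title = sprintf("Spearman correlation (%s mode%s)", mat$mode,
                      if (is.null(mat$subgroup)) "" else paste0(", ", mat$subgroup))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
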