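test_that("spearman_rho matches the rank-then-Pearson oracle, ties included", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(40, 30, 20, 10)), -1)
  x <- c(1, 2, 2, 4); y <- c(3, 1, 1, 2)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  withr::with_seed(21, {
    for (i in 1:30) {
      n <- sample(4:20, 1)
      x <- sample(1:6, n, replace = TRUE)   # heavy ties
      y <- rnorm(n)
      expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
    }
  })
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  withr::with_seed(33, {
    for (i in 1:20) {
      x <- rnorm(12); y <- rnorm(12)
      r <- spearman_rho(x, y)
      expect_equal(spearman_rho(exp(x), y), r)
      expect_equal(spearman_rho(x, y^3), r)
      expect_equal(spearman_rho(-x, y), -r)
    }
  })
})

test_that("spearman_p reproduces the published t-approximation convention", {
  expect_equal(spearman_p(0.22, 44), 0.1513, tolerance = 1e-3)
  expect_equal(spearman_p(0, 44), 1)
  p <- spearman_p(1, 44, method = "t_approx")
  expect_true(p > 0 && isTRUE(attr(p, "degenerate")))
})

test_that("the exact permutation p matches full enumeration for small n", {
  for (case in list(c(2, 1, 4, 3, 5), c(5, 4, 3, 2, 1), c(1, 3, 2, 5, 4))) {
    rho <- spearman_rho(seq_along(case), case)
    expect_equal(spearman_p(rho, length(case), "exact_permutation"),
                 oracle_perm_p(rho, length(case)))
  }
  rho6 <- spearman_rho(1:6, c(2, 1, 3, 5, 4, 6))
  expect_equal(spearman_p(rho6, 6, "exact_permutation"), oracle_perm_p(rho6, 6))
})

test_that("t approximation tracks the exact permutation p for n = 8-9", {
  withr::with_seed(14, {
    dev <- replicate(60, {
      n <- sample(8:9, 1)
      r <- spearman_rho(rnorm(n), rnorm(n))
      abs(spearman_p(r, n, "t_approx") - spearman_p(r, n, "exact_permutation"))
    })
    expect_lt(max(dev), 0.025)
    expect_lt(stats::median(dev), 0.01)
  })
})

test_that("mann_whitney_u matches symmetry, the worked example, and the oracle", {
  sym <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$U, 9 / 2)                      # U = n^2/2 for identical groups
  ex <- mann_whitney_u(c(1, 2, 3), c(10, 20, 30))
  expect_equal(ex$U, 0)
  expect_equal(ex$p_value, 0.1)                   # exact two-sided, C(6,3) labelings
  withr::with_seed(8, {
    for (i in 1:25) {
      # sizes kept inside the exact-enumeration branch (n_a * n_b <= 20)
      na <- sample(2:4, 1); nb <- sample(2:5, 1)
      a <- sample(1:8, na, replace = TRUE); b <- sample(1:8, nb, replace = TRUE)
      got <- mann_whitney_u(a, b)
      want <- oracle_mw(a, b)
      expect_equal(got$U, want$U)
      expect_equal(got$p_value, want$p)
      expect_equal(got$method, "exact_enumeration")
    }
  })
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("the large-sample branch agrees with the uncorrected normal test", {
  withr::with_seed(9, {
    a <- rnorm(15); b <- rnorm(12, 0.5)
    got <- mann_whitney_u(a, b)
    expect_equal(got$method, "normal_approx")
    ref <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE, exact = FALSE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  })
})

test_that("correlation matrices are symmetric with unit diagonal and recorded n", {
  ds <- load_paper_fixture()
  changes <- analysis_change_table(ds)
  m <- correlation_matrix(changes, "rate")
  mm <- as.matrix(m)
  expect_equal(mm, t(mm))
  expect_equal(unname(diag(mm)), rep(1, length(m$variables)))
  expect_equal(cormat_cell(m, "PASI", "IFN-g")$n, 44)
  expect_equal(cormat_cell(m, "PASI", "IFN-g/IL-4")$n, 42)
  expect_equal(cormat_cell(m, "IFN-g", "PASI")$rho,
               cormat_cell(m, "PASI", "IFN-g")$rho)
})

test_that("cells with too few complete pairs are undefined, not errors", {
  changes <- tibble::tibble(
    patient_id = c("a", "b", "c"), biologic = "ada",
    variable = "X", rate = c(1, NA, NA), difference = c(1, NA, NA)
  )
  changes <- dplyr::bind_rows(
    changes,
    tibble::tibble(patient_id = c("a", "b", "c"), biologic = "ada",
                   variable = "PASI", rate = c(0.1, 0.2, 0.3),
                   difference = c(1, 2, 3))
  )
  m <- correlation_matrix(changes, "rate")
  expect_true(is.na(cormat_cell(m, "PASI", "X")$rho))
  expect_equal(cormat_cell(m, "PASI", "X")$n, 1)
})

test_that("significance stars follow the published thresholds", {
  expect_equal(significance_stars(c(0.047, 0.009, 0.0009, 0.06, NA)),
               c("*", "**", "***", "", ""))
})

test_that("disease and biologic subgroupings produce the published strata", {
  ds <- load_paper_fixture()
  changes <- analysis_change_table(ds)
  by_dis <- subgroup_analyses(changes, ds, "by_disease")
  expect_setequal(names(by_dis),
                  c("PsO-only.rate", "PsO-only.difference",
                    "PsO+PsA.rate", "PsO+PsA.difference"))
  pso <- by_dis[["PsO-only.rate"]]
  expect_equal(pso$n_courses, 20)   # 10 PsO-only patients, 20 course rows
  by_bio <- subgroup_analyses(changes, ds, "by_biologic", modes = "rate")
  expect_equal(by_bio[["ust.rate"]]$n_courses, 15)
  expect_true(by_bio[["ris.rate"]]$low_n)  # 2 risankizumab courses
  # empty input yields an empty analysis list
  expect_length(subgroup_analyses(changes[0, ], ds, "by_biologic"), 0)
})

test_that("heatmap export emits one row per unordered off-diagonal pair", {
  changes <- tibble::tibble(
    patient_id = rep(letters[1:5], 2), biologic = "ada",
    variable = rep(c("PASI", "IFN-g"), each = 5),
    rate = c(1:5, c(2, 1, 4, 3, 5)), difference = c(1:5, c(2, 1, 4, 3, 5))
  )
  m <- correlation_matrix(changes, "rate")
  tab <- export_heatmap_table(m)
  expect_equal(nrow(tab), 1)
  expect_setequal(c(tab$var_a, tab$var_b), c("PASI", "IFN-g"))
  p <- plot_heatmap(m)
  expect_s3_class(p, "ggplot")
})

test_that("Benjamini-Hochberg adjustment is available but off by default", {
  ds <- load_paper_fixture()
  changes <- analysis_change_table(ds)
  m0 <- correlation_matrix(changes, "rate")
  expect_false("p_adjusted" %in% names(m0$cells))
  m1 <- correlation_matrix(changes, "rate", bh_correct = TRUE)
  off <- m1$cells$var_a != m1$cells$var_b & !is.na(m1$cells$p_value)
  expect_true(all(m1$cells$p_adjusted[off] >= m1$cells$p_value[off] - 1e-12))
})
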