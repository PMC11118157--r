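one_patient_changes <- function(rates, censored = NULL) {
  # rates: named list biologic -> named numeric vector of per-index rates
  rows <- list()
  for (b in names(rates)) {
    r <- rates[[b]]
    rows[[b]] <- tibble::tibble(
      patient_id = "p", biologic = b, index = names(r),
      baseline = 1, treated = 1 + r, reduction_rate = r, difference = r,
      status = "complete"
    )
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(censored)) {
    hit <- paste(out$biologic, out$index) %in% censored
    out$status[hit] <- "censored"
    out$reduction_rate[hit] <- NA_real_
    out$difference[hit] <- NA_real_
  }
  out
}

test_that("a biologic dominating on every oriented index scores strictly lower", {
  ch <- one_patient_changes(list(
    good = c("IFN-g" = -0.5, "IL-13" = 0.4, "IFN-g/IL-13" = -0.6),
    bad = c("IFN-g" = 0.2, "IL-13" = -0.1, "IFN-g/IL-13" = 0.3)
  ))
  sc <- score_biologics(ch)
  expect_lt(sc$composite_score[sc$biologic == "good"],
            sc$composite_score[sc$biologic == "bad"])
})

test_that("all-zero changes score at the neutral point and tie alphabetically", {
  ch <- one_patient_changes(list(
    ust = c("IFN-g" = 0, "IL-13" = 0),
    ada = c("IFN-g" = 0, "IL-13" = 0)
  ))
  sc <- score_biologics(ch)
  expect_equal(sc$composite_score, c(0, 0))
})

test_that("identical panels tie and are ranked alphabetically", {
  ds <- tiny_cohort()
  a <- ds$assays
  dup <- a[!is.na(a$biologic) & a$biologic == "ada" & a$patient_id == "p1", ]
  dup$biologic <- "gus"; dup$dose_ug_ml <- 1.2
  ds2 <- cohort_dataset(ds$patients, ds$courses, rbind(a, dup), validate = FALSE)
  rep <- rank_biologics(ds2, "p1")
  scores <- rep$ranking
  expect_equal(scores$composite_score[scores$biologic == "ada"],
               scores$composite_score[scores$biologic == "gus"])
  expect_true(which(rep$ranking$biologic == "ada") <
                which(rep$ranking$biologic == "gus"))
})

test_that("ranking is invariant to the input order of assay rows", {
  ds <- load_paper_fixture()
  base <- rank_biologics(ds, "E")
  withr::with_seed(4, {
    shuffled <- ds
    shuffled$assays <- ds$assays[sample(nrow(ds$assays)), ]
    again <- rank_biologics(shuffled, "E")
  })
  expect_equal(again$ranking$biologic, base$ranking$biologic)
  expect_equal(again$ranking$composite_score, base$ranking$composite_score)
})

test_that("an index censored everywhere does not reorder the others", {
  rates <- list(
    ada = c("IFN-g" = -0.3, "IL-13" = 0.2),
    sec = c("IFN-g" = -0.5, "IL-13" = 0.4)
  )
  sc0 <- score_biologics(one_patient_changes(rates))
  with_cens <- lapply(rates, function(r) c(r, "IFN-g/IL-4" = NA_real_))
  ch <- one_patient_changes(
    lapply(with_cens, function(r) { r["IFN-g/IL-4"] <- 0; r }),
    censored = c("ada IFN-g/IL-4", "sec IFN-g/IL-4")
  )
  sc1 <- score_biologics(ch)
  expect_equal(order(sc0$composite_score), order(sc1$composite_score))
  expect_match(sc1$omitted, "IFN-g/IL-4")
})

test_that("ranking requires at least two tested panels", {
  ds <- tiny_cohort()
  expect_error(rank_biologics(ds, "p2"), "at least 2")
  expect_error(rank_biologics(ds, "nobody"), "unknown patient")
})

test_that("patient H gets a finite three-way ranking", {
  rep <- rank_biologics(load_paper_fixture(), "H")
  expect_equal(nrow(rep$ranking), 3)
  expect_setequal(rep$ranking$biologic, c("ada", "sec", "ust"))
  expect_true(all(is.finite(rep$ranking$composite_score)))
  expect_equal(rep$recommended, rep$ranking$biologic[1])
})

test_that("patient E's scores match an independent spreadsheet-style recomputation", {
  # plain-arithmetic oracle from the printed source-table numbers: raw IFN-g
  # and IL-13 panels, printed ratio cells for the two ratio indices
  vals <- list(
    "IFN-g" = c(ind = 92.6, ada = 76.99, gus = 85.17, sec = 80.12),
    "IL-13" = c(ind = 1.53, ada = 1.53, gus = 1.34, sec = 1.71),
    "IFN-g/IL-13" = c(ind = 60.52, ada = 50.32, gus = 63.56, sec = 46.85),
    "IFN-g/IL-4" = c(ind = 7.61, ada = 8.18, gus = 6.9, sec = 6.19)
  )
  orient <- c("IFN-g" = 1, "IL-13" = -1, "IFN-g/IL-13" = 1, "IFN-g/IL-4" = 1)
  per_bio <- sapply(c("ada", "gus", "sec"), function(b) {
    mean(sapply(names(vals), function(ix) {
      rates <- (vals[[ix]][c("ada", "gus", "sec")] - vals[[ix]]["ind"]) / vals[[ix]]["ind"]
      orient[ix] * rates[b] / stats::sd(rates)
    }))
  })
  rep <- rank_biologics(load_paper_fixture(), "E")
  got <- stats::setNames(rep$ranking$composite_score, rep$ranking$biologic)
  expect_equal(got[names(per_bio)], per_bio, tolerance = 1e-12)
  expect_equal(rep$ranking$biologic, names(sort(per_bio)))
  expect_equal(rep$recommended, "sec")
})
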