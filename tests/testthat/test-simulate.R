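test_that("simulation is fully reproducible from the seed", {
  cfg <- simulation_config(n_patients = 8, seed = 5)
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_equal(d1$patients, d2$patients)
  expect_equal(d1$courses, d2$courses)
  expect_equal(d1$assays, d2$assays)
  d3 <- simulate_cohort(simulation_config(n_patients = 8, seed = 6))
  expect_false(identical(d1$assays$concentration_pg_ml,
                         d3$assays$concentration_pg_ml))
})

test_that("config validation rejects impossible parameters", {
  expect_error(simulation_config(target_rho = 1.5), "target_rho")
  expect_error(simulation_config(
    analyte_params = within(default_analyte_params(), induction_multiplier[1] <- -1)
  ), "positive")
  bad_eff <- default_biologic_effects()
  bad_eff$ada["IFN-g"] <- 0
  expect_error(simulation_config(biologic_effects = bad_eff), "positive")
  bad_name <- default_biologic_effects()
  names(bad_name)[1] <- "xyz"
  expect_error(simulation_config(biologic_effects = bad_name), "unknown biologic")
})

test_that("YAML configs round trip through read_simulation_config", {
  cfg <- simulation_config(n_patients = 7, target_rho = 0.3, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_patients = 7, target_rho = 0.3, seed = 9,
    biologics_per_patient = list("2" = 0.8, "3" = 0.2)
  ), path)
  cfg2 <- read_simulation_config(path)
  expect_equal(cfg2$n_patients, cfg$n_patients)
  expect_equal(cfg2$target_rho, cfg$target_rho)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(simulate_cohort(cfg2)$assays, simulate_cohort(cfg)$assays)
})

test_that("censor_lloq censors exactly the readings below the limit", {
  ds <- small_cohort(2)
  expect_equal(censor_lloq(ds, c("IFN-g" = 0))$assays, ds$assays)
  all_cens <- censor_lloq(ds, stats::setNames(rep(1e9, 5),
                                              default_analyte_params()$analyte))
  expect_true(all(all_cens$assays$censor == "below_range"))
  lim <- c("IL-13" = 2)
  out <- censor_lloq(ds, lim)
  brute <- sum(ds$assays$analyte == "IL-13" & ds$assays$censor == "observed" &
                 ds$assays$concentration_pg_ml < 2)
  expect_equal(
    sum(out$assays$censor == "below_range") - sum(ds$assays$censor == "below_range"),
    brute
  )
})

test_that("raising the LLOQ never decreases the censored count", {
  ds <- small_cohort(13)
  counts <- sapply(c(0.1, 0.5, 2, 10, 100), function(L) {
    sum(censor_lloq(ds, c("IL-4" = L))$assays$censor == "below_range")
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("default LLOQs censor a few percent of stimulated IL-4 readings", {
  ds <- simulate_cohort(simulation_config(n_patients = 150, seed = 31))
  il4 <- ds$assays[ds$assays$analyte == "IL-4" &
                     ds$assays$condition_kind != "control", ]
  frac <- mean(il4$censor == "below_range")
  expect_gt(frac, 0.001)
  expect_lt(frac, 0.06)
})

test_that("a null configuration yields a null PASI association", {
  null_eff <- lapply(default_biologic_effects(), function(e) { e[] <- 1; e })
  for (seed in c(1, 2)) {
    ds <- simulate_cohort(simulation_config(
      n_patients = 91, target_rho = 0, seed = seed, biologic_effects = null_eff
    ))
    ch <- analysis_change_table(ds, "IFN-g")
    rho <- cormat_cell(correlation_matrix(ch, "rate"), "PASI", "IFN-g")$rho
    expect_lt(abs(rho), 0.15)
  }
})

test_that("a 200-course cohort recovers the target rank correlation", {
  ds <- simulate_cohort(simulation_config(n_patients = 91, target_rho = 0.5, seed = 3))
  expect_gt(nrow(ds$courses), 150)
  ch <- analysis_change_table(ds, c("IFN-g", "IFN-g/IL-13"))
  rho <- cormat_cell(correlation_matrix(ch, "rate"), "PASI", "IFN-g/IL-13")$rho
  expect_gt(rho, 0.35)
  expect_lt(rho, 0.65)
})

test_that("suppressing only IFN-g leaves IL-4 null but couples IL-13 via the link", {
  eff <- lapply(default_biologic_effects(), function(e) { e[] <- 1; e["IFN-g"] <- 0.7; e })
  rho <- sapply(c(4, 5), function(seed) {
    ds <- simulate_cohort(simulation_config(n_patients = 91, seed = seed,
                                            biologic_effects = eff))
    ch <- analysis_change_table(ds, c("IL-4", "IL-13"))
    m <- correlation_matrix(ch, "rate")
    c(il4 = cormat_cell(m, "PASI", "IL-4")$rho,
      il13 = cormat_cell(m, "PASI", "IL-13")$rho)
  })
  # IL-4 plays no part in the copula link: null at sampling tolerance
  expect_true(all(abs(rho["il4", ]) < 0.2))
  # IL-13 enters the linked ratio's denominator, so it inherits a negative
  # association (as in the real cohort); it must not be null-centred
  expect_true(all(rho["il13", ] < -0.15))
})
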