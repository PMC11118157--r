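# shared fixtures and independent mini-oracles, built in code

small_cohort <- function(seed = 11, n_patients = 5) {
  simulate_cohort(simulation_config(n_patients = n_patients, seed = seed))
}

# a tiny hand-built 2-patient cohort with one censored reading
tiny_cohort <- function() {
  patients <- data.frame(
    patient_id = c("p1", "p2"), age = c(40, 50), sex = c("M", "F"),
    pso = TRUE, psa = c(FALSE, TRUE), comorbidities = c("", "HTN")
  )
  courses <- data.frame(
    patient_id = c("p1", "p1", "p2"), biologic = c("ada", "ust", "sec"),
    order_index = c(1L, 2L, 1L), pasi_before = c(10, 10, 20),
    pasi_after = c(2, 5, 1), months_to_outcome = c(6, 6, 12),
    tested_before_start = FALSE
  )
  grid <- expand.grid(
    patient_id = c("p1", "p2"), analyte = c("IFN-g", "IL-13", "IL-4"),
    stringsAsFactors = FALSE
  )
  induced <- data.frame(
    patient_id = grid$patient_id, condition_kind = "induced",
    biologic = NA_character_, dose_ug_ml = NA_real_, analyte = grid$analyte,
    concentration_pg_ml = c(100, 80, 2, 4, 5, 6), censor = "observed"
  )
  trt <- function(pid, bio, dose, conc, cens = rep("observed", 3)) {
    data.frame(
      patient_id = pid, condition_kind = "induced_plus_biologic",
      biologic = bio, dose_ug_ml = dose, analyte = c("IFN-g", "IL-13", "IL-4"),
      concentration_pg_ml = conc, censor = cens
    )
  }
  assays <- rbind(
    induced,
    trt("p1", "ada", 4, c(60, 3, 5)),
    trt("p1", "ust", 0.25, c(90, 2.5, NA), c("observed", "observed", "below_range")),
    trt("p2", "sec", 34, c(50, 6, 7))
  )
  cohort_dataset(patients, courses, assays)
}

# independent oracle: Spearman rho as Pearson on midranks
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# independent oracle: exact two-sided permutation p for untied ranks, by
# explicit recursion over all orderings (no shared code with the package)
oracle_perm_p <- function(rho_obs, n) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perms(seq_len(n)), function(p) {
    suppressWarnings(stats::cor(p, seq_len(n), method = "pearson"))
  }, numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# independent oracle: exact two-sided Mann-Whitney p by enumerating every
# C(n, na) group labelling of the pooled sample
oracle_mw <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_all <- apply(utils::combn(length(pooled), na), 2,
                 function(s) sum(r[s]) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9))
  list(U = u_obs, p = min(1, p))
}
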