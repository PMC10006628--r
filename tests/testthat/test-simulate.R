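test_that("cause-1 probability matches the mixture asymptote", {
  cfg <- sim_config(p_asym = 0.3, censor_lo = Inf, censor_hi = Inf)
  out <- simulate_competing_events(rep(0, 20000), cfg, seed = 101)
  # with no censoring every patient resolves to cause 1 or 2
  expect_true(all(out$cause %in% 1:2))
  expect_equal(mean(out$cause == 1), 0.3, tolerance = 0.02)
})

test_that("cause-1 times follow the closed-form subdistribution CDF", {
  # F1(t|x) = 1 - (1 - p(1 - exp(-lambda1 t)))^exp(x)
  cfg <- sim_config(beta1 = log(2), p_asym = 0.3, lambda1 = 0.2,
                    censor_lo = Inf, censor_hi = Inf)
  F1 <- function(t, lp) 1 - (1 - cfg$p_asym * (1 - exp(-cfg$lambda1 * t)))^exp(lp)
  out <- simulate_competing_events(rep(log(2), 5000), cfg, seed = 7)
  emp <- mean(out$time <= 5 & out$cause == 1)
  expect_equal(emp, F1(5, log(2)), tolerance = 0.02)
})

test_that("a null coefficient gives indistinguishable cause-1 incidence", {
  cfg <- sim_config(beta1 = 0, p_asym = 0.3, censor_lo = Inf,
                    censor_hi = Inf)
  x <- rep(c(0, 1), each = 5000)
  out <- simulate_competing_events(0 * x, cfg, seed = 33)
  c0 <- cif_aalen_johansen(out[x == 0, ])
  c1 <- cif_aalen_johansen(out[x == 1, ])
  grid <- seq(0.5, 30, by = 0.5)
  expect_lt(max(abs(cif_at(c0, grid) - cif_at(c1, grid))), 0.05)
})

test_that("non-finite linear predictors are rejected by patient", {
  cfg <- sim_config()
  expect_error(simulate_competing_events(c(0, NA, 0, Inf), cfg), "2, 4")
})

test_that("cohort generation is reproducible and honours its truth record", {
  cfg <- small_cfg(seed = 5L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$somamer_table$rfu, b$somamer_table$rfu)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$clinical, b$clinical)
  expect_setequal(unique(a$truth$group), 1:2)
  expect_length(a$truth$group, cfg$n_patients)
  expect_length(a$truth$informative, cfg$n_informative)
  expect_equal(nrow(a$outcomes), cfg$n_patients)
  expect_equal(sum(a$somamer_table$sample_meta$sample_type == "study"),
               cfg$n_patients)
  expect_equal(ncol(a$somamer_table$rfu),
               cfg$n_somamers + cfg$n_hyb_controls)
})

test_that("the configuration rejects impossible designs", {
  expect_error(sim_config(n_informative = 500, n_somamers = 40,
                          removal_count = 4, dup2_count = 3, dup3_count = 1),
               "n_informative")
  expect_error(sim_config(p_asym = 1.2), "p_asym")
  expect_error(sim_config(censor_lo = 10, censor_hi = 5), "censor_lo")
})

test_that("informative proteins separate the latent groups after the full assay layer", {
  # keep the informative fraction modest so per-dilution median
  # normalization is not dragged by the group shift itself
  coh <- simulate_cohort(sim_config(n_patients = 150, n_somamers = 120,
                                    removal_count = 6, dup2_count = 4,
                                    dup3_count = 2, n_informative = 8,
                                    n_plates = 2, seed = 9L, delta = 1.5))
  lg <- log2_transform(aggregate_to_proteins(remove_flagged(
    normalize_pipeline(coh$somamer_table)$table)))
  lg <- lg[match(coh$outcomes$patient_id, rownames(lg)), ]
  g <- coh$truth$group
  gaps <- vapply(coh$truth$informative,
                 function(p) mean(lg[g == 2, p]) - mean(lg[g == 1, p]),
                 numeric(1))
  expect_true(all(gaps > 1.0))      # planted shift is 1.5
  noise <- setdiff(colnames(lg), coh$truth$informative)
  gaps0 <- vapply(noise, function(p) mean(lg[g == 2, p]) - mean(lg[g == 1, p]),
                  numeric(1))
  expect_lt(max(abs(gaps0)), 0.5)
})

test_that("missingness injection masks at the requested rate and is reversible", {
  coh <- simulate_cohort(small_cfg(seed = 2L, clinical_missing_rate = 0))
  clin <- coh$clinical
  expect_identical(attr(clin, "n_masked"), 0L)

  rate <- 53 / 6858
  big <- clin[rep(seq_len(nrow(clin)), length.out = 254), ]
  big$patient_id <- sprintf("PAT%04d", seq_len(254))
  n_cells <- 254 * 27
  expect_equal(n_cells, 6858)
  # masked counts behave binomially: almost all seeds land in the central
  # 99% range, and the mean tracks n * rate
  counts <- vapply(1:20, function(s) {
    attr(inject_missing(big, rate, seed = s), "n_masked")
  }, integer(1))
  in_range <- counts >= qbinom(0.005, n_cells, rate) &
    counts <= qbinom(0.995, n_cells, rate)
  expect_gte(mean(in_range), 0.9)
  expect_equal(mean(counts), n_cells * rate, tolerance = 0.25)
  # identical mask on rerun under the same seed
  masked <- inject_missing(big, rate, seed = 3)
  again <- inject_missing(big, rate, seed = 3)
  expect_identical(attr(masked, "mask"), attr(again, "mask"))
  # truth retained
  expect_identical(attr(masked, "complete"), big)
  expect_error(inject_missing(big, 1), "fully missing")
})

test_that("group model recovers beta1 and its CI covers the true SHR over seeds", {
  recovered <- 0L
  covered <- 0L
  n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    cfg <- small_cfg(n_patients = 2000, beta1 = log(2), p_asym = 0.25,
                     seed = 100L + s)
    coh <- simulate_cohort(cfg)
    fit <- group_risk_model(coh$truth$group, coh$outcomes)
    if (abs(fit$coef[["group2"]] - log(2)) <= 0.15) recovered <- recovered + 1L
    if (fit$ci_lower[["group2"]] <= 2 && 2 <= fit$ci_upper[["group2"]]) {
      covered <- covered + 1L
    }
  }
  expect_gte(recovered / n_seeds, 0.9)
  expect_gte(covered / n_seeds, 0.9)
})

test_that("with no group shift the planted groups are unrecoverable", {
  cfg <- small_cfg(n_patients = 1000, delta = 0, beta1 = 0, seed = 77L)
  coh <- simulate_cohort(cfg)
  lg <- log2_transform(aggregate_to_proteins(remove_flagged(
    normalize_pipeline(coh$somamer_table)$table)))
  lg <- lg[match(coh$outcomes$patient_id, rownames(lg)), ]
  z <- apply_standardization(protein_matrix(lg, "log2"),
                             fit_standardization(protein_matrix(lg, "log2")))
  km <- kmeans_fit(z, 2, seed = 1)
  expect_lt(ari(km$labels, coh$truth$group), 0.1)
})
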