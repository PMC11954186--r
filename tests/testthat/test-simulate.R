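test_that("same (config, seed) gives identical cohorts and coverage", {
  cfg <- simulation_config(n_individuals = 300,
                           marker_effects = data.frame(
                             name = "mk", type = "binary", prevalence = 0.4,
                             displacement = 0.1, amplitude_change = -0.05,
                             acrophase_shift = 0.2),
                           death_spec = list(rate = 0.1, amplitude_ratio = 0.8))
  a <- generate_cohort(cfg, seed = 77)
  b <- generate_cohort(cfg, seed = 77)
  expect_identical(a, b)
  ca <- generate_coverage(a$cohort, seed = 77)
  cb <- generate_coverage(b$cohort, seed = 77)
  expect_identical(ca, cb)
  d <- generate_cohort(cfg, seed = 78)
  expect_false(identical(a$cohort$outcome, d$cohort$outcome))
})

test_that("noiseless monthly means follow the configured sinusoid", {
  cfg <- simulation_config(n_individuals = 2400, amplitude_true = 0.5,
                           acrophase_true = 0, noise_sd = 1e-9,
                           covariate_specs = NULL)
  sim <- generate_cohort(cfg, seed = 5)
  mu <- tapply(sim$cohort$outcome, sim$cohort$month, mean)
  m <- as.integer(names(mu))
  expect_equal(as.numeric(mu), 0.5 * cos(2 * pi * (m - 1) / 12),
               tolerance = 1e-6)
})

test_that("zero amplitude gives month-constant means", {
  cfg <- simulation_config(n_individuals = 2400, amplitude_true = 0,
                           noise_sd = 1e-9, covariate_specs = NULL,
                           baseline_mean = 2)
  sim <- generate_cohort(cfg, seed = 5)
  mu <- tapply(sim$cohort$outcome, sim$cohort$month, mean)
  expect_lt(diff(range(mu)), 1e-6)
  expect_equal(unname(mu[1]), 2, tolerance = 1e-6)
})

test_that("truth record betas invert the amplitude/acrophase transforms", {
  for (A in c(0.092, 0.5)) for (phi in c(-0.14, 1.1, pi)) {
    cfg <- simulation_config(n_individuals = 10, amplitude_true = A,
                             acrophase_true = phi, covariate_specs = NULL)
    tr <- generate_cohort(cfg, seed = 1)$truth
    expect_equal(sqrt(tr$beta2_true^2 + tr$beta3_true^2), A, tolerance = 1e-14)
    if (A > 0)
      expect_equal(atan2(tr$beta3_true, tr$beta2_true), phi, tolerance = 1e-12)
  }
})

test_that("generated covariate moments match the configuration (n = 10000)", {
  cfg <- simulation_config(n_individuals = 10000)
  sim <- generate_cohort(cfg, seed = 123)
  spec <- default_covariate_specs()
  for (i in seq_len(nrow(spec))) {
    v <- sim$cohort[[spec$name[i]]]
    if (spec$distribution[i] == "normal") {
      se_mean <- spec$sd[i] / sqrt(10000)
      expect_lt(abs(mean(v) - spec$mean[i]), 3 * se_mean)
      expect_lt(abs(sd(v) - spec$sd[i]), 3 * spec$sd[i] / sqrt(2 * 9999))
    } else {
      p <- spec$prevalence[i]
      expect_lt(abs(mean(v) - p), 3 * sqrt(p * (1 - p) / 10000))
    }
  }
})

test_that("noiseless interaction recovery: additive amplitude change -0.2", {
  cfg <- simulation_config(
    n_individuals = 1200, amplitude_true = 0.5, acrophase_true = 0.3,
    noise_sd = 1e-9, covariate_specs = NULL,
    marker_effects = data.frame(name = "mk", type = "binary",
                                prevalence = 0.5, displacement = 0,
                                amplitude_change = -0.2, acrophase_shift = 0))
  sim <- generate_cohort(cfg, seed = 9)
  fit <- fit_interaction(sim$cohort$outcome, sim$cohort$month, sim$cohort$mk)
  s <- summarize_interaction(fit)
  expect_equal(as.data.frame(s)["amplitude", "estimate"], -0.2, tolerance = 1e-6)
  expect_equal(as.data.frame(s)["acrophase", "estimate"], 0, tolerance = 1e-6)
  expect_equal(unname(fit$beta[c("beta4", "beta5")]),
               c(sim$truth$markers$beta4_true, sim$truth$markers$beta5_true),
               tolerance = 1e-6)
})

test_that("ill-posed effect sizes are rejected at configuration time", {
  expect_error(simulation_config(
    amplitude_true = 0.1,
    marker_effects = data.frame(name = "mk", type = "binary", prevalence = 0.5,
                                displacement = 0, amplitude_change = -0.2,
                                acrophase_shift = 0)), "negative")
  expect_error(simulation_config(
    disease_specs = data.frame(name = "d", incidence = 0.1,
                               amplitude_ratio = -1)), "ratio")
})

test_that("coverage: noiseless equal-read ratios preserve abundance order", {
  cfg <- simulation_config(n_individuals = 200, covariate_specs = NULL)
  sim <- generate_cohort(cfg, seed = 3)
  cov <- generate_coverage(sim$cohort, seed = 3, reads_sdlog = 0,
                           coverage_noise_sd = 0)
  ratio <- cov$mt_mean_coverage / cov$total_mapped_reads
  expect_equal(order(ratio), order(sim$cohort$latent_abundance))
  # with defaults the mean mitochondrial coverage is in the ~0.66X regime
  cov2 <- generate_coverage(sim$cohort, seed = 3)
  expect_gt(mean(cov2$mt_mean_coverage), 0.3)
  expect_lt(mean(cov2$mt_mean_coverage), 1.2)
})

test_that("a 10x inflated abundance is caught by the downstream IQR filter", {
  cfg <- simulation_config(n_individuals = 300, covariate_specs = NULL)
  sim <- generate_cohort(cfg, seed = 21)
  sim$cohort$latent_abundance[17] <- sim$cohort$latent_abundance[17] * 10
  cov <- generate_coverage(sim$cohort, seed = 21)
  ab <- mtdna_abundance(data.frame(sample_id = cov$sample_id,
                                   mt_mean_coverage = cov$mt_mean_coverage,
                                   total_mapped_reads = cov$total_mapped_reads))
  expect_false(ab$qc_pass[17])
  expect_identical(ab$qc_pass, oracle_iqr_mask(ab$ratio, 4))
})

test_that("death and follow-up generation respect the configured ranges", {
  cfg <- simulation_config(n_individuals = 4000, covariate_specs = NULL,
                           death_spec = list(rate = 0.065,
                                             amplitude_ratio = 0.772,
                                             followup_range = c(0.01, 15.5)))
  sim <- generate_cohort(cfg, seed = 2)
  expect_true(all(sim$cohort$death %in% 0:1))
  expect_lt(abs(mean(sim$cohort$death) - 0.065),
            3 * sqrt(0.065 * 0.935 / 4000))
  expect_true(all(sim$cohort$follow_up >= 0.01 & sim$cohort$follow_up <= 15.5))
  expect_equal(sim$truth$death$delta_amplitude, (0.772 - 1) * 0.092)
})
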