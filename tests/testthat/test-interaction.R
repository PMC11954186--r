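test_that("noiseless constructions recover the interaction coefficients", {
  m <- rep(1:12, each = 5)
  theta <- 2 * pi * (m - 1) / 12
  mk <- rep(0:1, 30)
  # group amplitudes 0.5 vs 0.3, common phase 0
  y <- (0.5 - 0.2 * mk) * cos(theta)
  fit <- fit_interaction(y, m, mk)
  expect_equal(unname(fit$beta), c(0, 0.5, 0, -0.2, 0), tolerance = 1e-10)
  # phase shift pi/6 at constant amplitude 0.5
  y2 <- 0.5 * cos(theta - mk * pi / 6)
  fit2 <- fit_interaction(y2, m, mk)
  expect_equal(fit2$beta[["beta4"]], 0.5 * cos(pi / 6) - 0.5, tolerance = 1e-10)
  expect_equal(fit2$beta[["beta5"]], 0.25, tolerance = 1e-10)
})

test_that("summarize_interaction: identity, phase-shift and amplitude-drop cases", {
  m <- rep(1:12, each = 5)
  theta <- 2 * pi * (m - 1) / 12
  mk <- rep(0:1, 30)
  # beta4 = beta5 = 0 -> no change in anything
  set.seed(1)
  y0 <- 0.5 * cos(theta) + mk * 0.3
  s0 <- summarize_interaction(fit_interaction(y0, m, mk))
  df0 <- as.data.frame(s0)
  expect_equal(df0["amplitude", "estimate"], 0, tolerance = 1e-10)
  expect_equal(df0["acrophase", "estimate"], 0, tolerance = 1e-10)
  expect_equal(df0["displacement", "estimate"], 0.3, tolerance = 1e-10)
  # pure phase shift pi/6 -> delta amplitude 0, delta acrophase 1 month
  y2 <- 0.5 * cos(theta - mk * pi / 6)
  s2 <- summarize_interaction(fit_interaction(y2, m, mk))
  df2 <- as.data.frame(s2)
  expect_equal(df2["amplitude", "estimate"], 0, tolerance = 1e-10)
  expect_equal(df2["acrophase", "estimate"], 1, tolerance = 1e-10)
  expect_equal(attr(s2, "delta_acrophase_pct_month"), 100, tolerance = 1e-8)
  # amplitude drop 0.5 -> 0.3 against reference 0.5 is -40%
  y3 <- (0.5 - 0.2 * mk) * cos(theta)
  s3 <- summarize_interaction(fit_interaction(y3, m, mk),
                              reference_amplitude = 0.5)
  expect_equal(attr(s3, "delta_amplitude_pct"), -40, tolerance = 1e-8)
})

test_that("constant marker and missing markers are handled", {
  m <- rep(1:12, each = 3)
  y <- rnorm(36)
  expect_error(fit_interaction(y, m, rep(1, 36)), "constant")
  mk <- c(rep(NA, 6), rep(0:1, 15))
  fit <- fit_interaction(y, m, mk)
  expect_equal(fit$n_used, 30)
  expect_equal(fit$n_dropped, 6)
})

test_that("mutual adjustment keeps co-markers as main effects only", {
  set.seed(4)
  n <- 600
  m <- sample.int(12, n, replace = TRUE)
  theta <- 2 * pi * (m - 1) / 12
  other <- rnorm(n)
  mk <- rnorm(n)
  y <- 0.3 * cos(theta) + 0.5 * other + rnorm(n)
  fit <- fit_interaction(y, m, mk, mutual_adjust = data.frame(other = other))
  expect_true("other" %in% names(fit$coefficients))
  expect_false(any(grepl("other:", names(fit$coefficients))))
  # adjusting for the true confounder-free main effect should not bias beta1
  expect_lt(abs(fit$beta[["beta1"]]), 3 * sqrt(fit$sub_vcov[1, 1]))
})

test_that("null interaction z-scores are centred standard normal", {
  st <- null_interaction_stats(n = 400, reps = 300, seed = 12)
  expect_true(all(abs(colMeans(st$z)) < 0.1))
  expect_true(all(abs(apply(st$z, 2, sd) - 1) < 0.15))
  for (j in 1:3)
    expect_gt(suppressWarnings(ks.test(st$p[, j], "punif"))$p.value, 0.01)
})

test_that("exact and linearized definitions agree to first order", {
  m <- rep(1:12, each = 10)
  theta <- 2 * pi * (m - 1) / 12
  mk <- rep(0:1, 60)
  rel_diff_amp <- rel_diff_acro <- numeric(0)
  for (eff in c(0.2, 0.1, 0.05, 0.025, 0.0125)) {
    y <- (0.5 + eff * mk) * cos(theta - mk * eff)
    fit <- fit_interaction(y, m, mk)
    ex <- as.data.frame(summarize_interaction(fit, method = "exact"))
    ln <- as.data.frame(summarize_interaction(fit, method = "linearized"))
    rel_diff_amp <- c(rel_diff_amp,
                      abs(ex["amplitude", 1] - ln["amplitude", 1]) / eff)
    rel_diff_acro <- c(rel_diff_acro,
                       abs(ex["acrophase", 1] - ln["acrophase", 1]) /
                         (eff * 12 / (2 * pi)))
  }
  # relative disagreement shrinks as the interaction effect shrinks
  expect_true(all(diff(rel_diff_amp) < 0))
  expect_true(all(diff(rel_diff_acro) < 0))
  expect_lt(rel_diff_amp[5], 0.05)
  expect_lt(rel_diff_acro[5], 0.05)
})

test_that("incident disease coding: controls, incident, prevalent", {
  recruit <- as.Date("2008-06-01")
  ev <- as.Date(c(NA, "2010-06-01", "2007-06-01", "2008-06-01"))
  expect_identical(incident_disease_exposure(ev, rep(recruit, 4)),
                   c(0L, 1L, NA_integer_, NA_integer_))
})

test_that("composite phenotypes count groups with NA propagation", {
  g <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 0, 0), c(NA, 0, 0), c(1, NA, 0))
  comp <- composite_disease_phenotypes(g)
  expect_equal(comp$any_disease, c(1L, 1L, 0L, NA_integer_, 1L))
  # one unknown group cannot by itself reach two diseases -> definite 0
  expect_equal(comp$multiple_diseases, c(0L, 1L, 0L, 0L, NA_integer_))
  expect_error(composite_disease_phenotypes(matrix(nrow = 3, ncol = 0)),
               "at least one")
})

test_that("run_scan: bookkeeping, determinism, sorting, degenerate markers", {
  set.seed(31)
  n <- 400
  cfg <- simulation_config(n_individuals = n, amplitude_true = 0.4,
                           acrophase_true = 0, noise_sd = 0.5,
                           covariate_specs = NULL,
                           marker_effects = data.frame(
                             name = "hit", type = "binary", prevalence = 0.5,
                             displacement = 0.5, amplitude_change = -0.3,
                             acrophase_shift = 0))
  sim <- generate_cohort(cfg, seed = 31)
  cohort <- sim$cohort
  markers <- data.frame(hit = cohort$hit,
                        null1 = rnorm(n), null2 = rnorm(n),
                        dup = cohort$hit,
                        const = rep(1, n))
  expect_warning(scan <- run_scan(cohort, markers, scan_settings()),
                 "degenerate.*const")
  expect_equal(attr(scan, "n_tests"), 15)  # 3 x 5 declared markers
  expect_equal(nrow(scan), 4)
  expect_equal(scan$p_min, sort(scan$p_min))
  # duplicated marker column gives identical rows
  r1 <- scan[scan$marker == "hit", -1]
  r2 <- scan[scan$marker == "dup", -1]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
  # Bonferroni recount
  expect_identical(scan$significant,
                   pmin(1, scan$p_min * attr(scan, "n_tests")) < 0.05)
  expect_true(scan$significant[scan$marker == "hit"][1])
  # determinism
  scan2 <- suppressWarnings(run_scan(cohort, markers, scan_settings()))
  expect_identical(as.data.frame(scan), as.data.frame(scan2))
  expect_error(run_scan(cohort, markers[, 0], scan_settings()), "empty")
})

test_that("fixed-threshold policy mirrors the labWAS/PWAS convention", {
  set.seed(32)
  n <- 300
  cohort <- data.frame(outcome = rnorm(n),
                       month = sample.int(12, n, replace = TRUE))
  markers <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  st <- scan_settings(threshold_policy = "fixed", fixed_threshold = 0.0001)
  scan <- run_scan(cohort, markers, st)
  expect_identical(scan$significant, scan$p_min < 0.0001)
  expect_error(scan_settings(threshold_policy = "fixed"), "fixed_threshold")
})

test_that("marker principal components are appended as adjustment columns", {
  set.seed(33)
  n <- 200
  f <- rnorm(n)
  cohort <- data.frame(outcome = rnorm(n),
                       month = sample.int(12, n, replace = TRUE))
  markers <- data.frame(a = f + rnorm(n, 0, 0.3), b = f + rnorm(n, 0, 0.3),
                        c = rnorm(n), d = rnorm(n))
  scan <- run_scan(cohort, markers, scan_settings(marker_pcs = 3))
  expect_equal(nrow(scan), 4)
  expect_true(all(scan$n_used == n))
})

test_that("mortality interaction recovers the generated amplitude deficit", {
  cfg <- simulation_config(
    n_individuals = 8000, amplitude_true = 0.3, acrophase_true = -0.14,
    noise_sd = 1, covariate_specs = NULL,
    death_spec = list(rate = 0.3, amplitude_ratio = 0.8,
                      followup_range = c(0.01, 15.5)))
  sim <- generate_cohort(cfg, seed = 55)
  s <- mortality_interaction(sim$cohort, reference_amplitude = 0.3)
  df <- as.data.frame(s)
  truth_dA <- (0.8 - 1) * 0.3
  expect_lt(abs(df["amplitude", "estimate"] - truth_dA),
            3 * df["amplitude", "se"])
  # percent scale: about -20% of the reference amplitude
  expect_lt(abs(attr(s, "delta_amplitude_pct") - (-20)),
            3 * attr(s, "delta_amplitude_pct_se"))
  # zero deaths -> constant marker -> error
  sim$cohort$death <- 0
  expect_error(mortality_interaction(sim$cohort), "constant")
})

test_that("z-score correlations: duplicated, negated, independent columns", {
  scan <- data.frame(amp_z = c(1.2, -0.5, 0.3, 2.2),
                     acro_z = c(1.2, -0.5, 0.3, 2.2),
                     disp_z = -c(1.2, -0.5, 0.3, 2.2))
  r <- zscore_correlations(scan)
  expect_equal(unname(diag(r)), c(1, 1, 1))
  expect_equal(r["amplitude", "acrophase"], 1)
  expect_equal(r["amplitude", "displacement"], -1)
  set.seed(6)
  ind <- data.frame(amp_z = rnorm(500), acro_z = rnorm(500), disp_z = rnorm(500))
  expect_true(all(abs(zscore_correlations(ind)[upper.tri(r)]) < 0.15))
  degen <- data.frame(amp_z = rep(1, 5), acro_z = rnorm(5), disp_z = rnorm(5))
  expect_warning(rz <- zscore_correlations(degen), "zero-variance")
  expect_true(is.na(rz["amplitude", "acrophase"]))
})

test_that("lambda_gc: exact cases and monotonicity", {
  expect_equal(lambda_gc(rep(0.5, 10)), 1, tolerance = 1e-12)
  set.seed(14)
  p <- runif(5000)
  expect_gt(lambda_gc(p / 2), lambda_gc(p))
  expect_error(lambda_gc(numeric(0)), "no P-values")
  expect_error(lambda_gc(c(0.5, 0)), "in \\(0, 1\\]")
})
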