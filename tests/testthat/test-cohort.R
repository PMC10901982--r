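# Synthetic cohort generator: calibration, copula fidelity, survival
# process correctness, determinism.

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(n_subjects = 0), "positive integer")
  bad <- default_pollutant_spearman()
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- -0.999 # forces a negative eigenvalue
  expect_error(cohort_config(pollutant_spearman = bad), "positive definite")
  ns <- default_pollutant_spearman()
  ns[1, 2] <- 0.5
  expect_error(cohort_config(pollutant_spearman = ns), "symmetric")
  expect_error(cohort_config(apoe_freqs = c(e2 = 0.5, e3 = 0.4, e4 = 0.3)),
               "sum to 1")
  expect_error(cohort_config(pollutant_iqrs = c(2.3, -1, 6.9, 12)),
               "IQRs must be positive")
})

test_that("exposure marginals match configured mean and IQR", {
  cfg <- test_config(1e5, seed = 11)
  ex <- withr::with_seed(11, generate_exposures(cfg))
  # printed marginals: mean (IQR) 9.9 (2.3) for PM2.5, etc.
  expect_lt(abs(mean(ex$pm25) - 9.9), 0.05)
  expect_lt(abs(IQR(ex$pm25) - 2.3), 0.05)
  means <- colMeans(ex)
  iqrs <- vapply(ex, IQR, numeric(1))
  expect_lt(max(abs(means / cfg$pollutant_means - 1)), 0.01)
  expect_lt(max(abs(iqrs / cfg$pollutant_iqrs - 1)), 0.02)
  expect_true(all(ex >= 0))
  # right skew of a log-normal marginal
  expect_gt(mean(ex$nox) , median(ex$nox))
})

test_that("gaussian copula reproduces the target Spearman structure", {
  # independence case
  cfg_i <- test_config(1e5, pollutant_spearman = diag(4))
  ex_i <- withr::with_seed(21, generate_exposures(cfg_i))
  sp_i <- spearman_matrix(ex_i)
  expect_lt(max(abs(sp_i[upper.tri(sp_i)])), 0.02)
  # strong-dependence case, entrywise fidelity
  m <- default_pollutant_spearman()
  m[1, 2] <- m[2, 1] <- 0.9
  cfg_d <- test_config(1e5, pollutant_spearman = m)
  ex_d <- withr::with_seed(22, generate_exposures(cfg_d))
  sp_d <- spearman_matrix(ex_d)
  expect_lt(abs(sp_d["pm25", "pm10"] - 0.9), 0.02)
  expect_lt(max(abs(sp_d - m)), 0.02)
})

test_that("SNP dosages and APOE groups follow the configured frequencies", {
  panel <- default_prs_panel()
  panel$freq[] <- 0
  cfg0 <- test_config(200, snp_panel = panel)
  g0 <- withr::with_seed(31, generate_genetics(cfg0))
  expect_true(all(g0[, panel$snp_id] == 0))

  cfg <- test_config(1e5, apoe_freqs = c(e2 = 0.07, e3 = 0.78, e4 = 0.15))
  g <- withr::with_seed(32, generate_genetics(cfg))
  ap <- apoe_from_genotypes(g$rs429358, g$rs7412)
  # Hardy-Weinberg: P(e4/e4) = q^2 = 0.0225
  expect_lt(abs(mean(ap$apoe_dosage == 2) - 0.0225), 0.003)

  # default calibration vs printed dosage-group shares 71.8/23.4/2.3
  # (normalized over observed categories: 73.6/24.0/2.4)
  cfgd <- test_config(1e5)
  gd <- withr::with_seed(33, generate_genetics(cfgd))
  apd <- apoe_from_genotypes(gd$rs429358, gd$rs7412)
  shares <- as.numeric(prop.table(table(apd$apoe_dosage)))
  expect_lt(abs(shares[1] - 0.736), 0.01)
  expect_lt(abs(shares[2] - 0.240), 0.01)
  expect_lt(abs(shares[3] - 0.024), 0.01)

  badp <- default_prs_panel()
  badp$freq[1] <- 1.2
  expect_error(cohort_config(snp_panel = badp), "frequencies")
})

test_that("null-effect survival matches the exponential closed form", {
  # no staggering, no early censoring, zero effects:
  # P(event) = 1 - exp(-h * admin_end)
  cfg <- cohort_config(n_subjects = 4e4, true_effects = zero_effects(),
                       baseline_hazard = 0.01, admin_end = 10,
                       recruitment_span = 0, early_censor_frac = 0,
                       seed = 41)
  coh <- simulate_cohort(cfg)
  expect_lt(abs(mean(coh$event) - (1 - exp(-0.01 * 10))), 0.005)
  # Kaplan-Meier equals exp(-ht) pointwise within an MC band
  sf <- survival::survfit(survival::Surv(followup_years, event) ~ 1,
                          data = coh)
  at <- sapply(c(2, 5, 8), function(tt) sf$surv[max(which(sf$time <= tt))])
  expect_lt(max(abs(at - exp(-0.01 * c(2, 5, 8)))), 0.01)
})

test_that("doubling the relative hazard doubles the event rate ratio", {
  te <- zero_effects()
  te$covariates["sex_male"] <- log(2)
  cfg <- cohort_config(n_subjects = 6e4, true_effects = te,
                       baseline_hazard = 0.005, seed = 42)
  coh <- simulate_cohort(cfg)
  d <- coh
  d$x <- as.integer(d$sex == "male")
  rr <- exp(rate_ratio_oracle(d))
  expect_lt(abs(rr - 2), 0.25) # MC error at ~1,000 events
})

test_that("default calibration yields the printed event horizon", {
  cfg <- cohort_config(n_subjects = 1e5, seed = 43)
  coh <- simulate_cohort(cfg)
  s <- summarize_cohort(coh)
  expect_lt(abs(s$median_followup - 13.4), 0.2)
  expect_gt(s$event_rate, 0.011)
  expect_lt(s$event_rate, 0.019)
})

test_that("cohorts are bit-identical given config + seed", {
  cfg <- test_config(500, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  attributes(a) <- attributes(a)[c("names", "row.names", "class")]
  attributes(b) <- attributes(b)[c("names", "row.names", "class")]
  expect_identical(a, b)
})

test_that("summarize_cohort handles degenerate inputs", {
  expect_error(summarize_cohort(data.frame()), "empty")
  one <- data.frame(pm25 = 1, pm10 = 2, no2 = 3, nox = 4,
                    followup_years = 2.0, event = 0L)
  expect_warning(s1 <- summarize_cohort(one), "undefined")
  expect_equal(s1$person_years, 2.0)
  const <- data.frame(pm25 = rep(1, 10), pm10 = rnorm(10, 15),
                      no2 = rnorm(10, 18), nox = rnorm(10, 27),
                      followup_years = rep(1, 10),
                      event = rep(0L, 10))
  expect_warning(s <- summarize_cohort(const), "constant")
  expect_true(is.na(s$spearman["pm25", "pm10"]))
  expect_equal(unname(s$pollutant_iqrs["pm25"]), 0)
})

test_that("cohort round-trips through delimited text", {
  coh <- simulate_cohort(test_config(120, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$pm25, coh$pm25, tolerance = 1e-8)
  expect_identical(levels(back$sex), levels(coh$sex))
  expect_identical(back$event, coh$event)
})

test_that("confounding knob links TDI to the exposures", {
  cfg0 <- test_config(5000, seed = 7, confounding = 0)
  cfg1 <- test_config(5000, seed = 7, confounding = 1)
  c0 <- simulate_cohort(cfg0)
  c1 <- simulate_cohort(cfg1)
  r0 <- cor(c0$tdi, attr(c0, "truth")$score)
  r1 <- cor(c1$tdi, attr(c1, "truth")$score)
  expect_lt(abs(r0), 0.05)
  expect_gt(r1, 0.2)
})
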