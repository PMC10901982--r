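# Cox model wrapper: oracle equivalence, input validation, recovery,
# scale invariance, CI coverage, per-IQR and quartile effect estimates.

test_that("fit_cox matches the brute-force partial-likelihood maximizer", {
  # 3-subject instance, all events, binary covariate with a finite
  # partial-likelihood maximizer
  d3 <- data.frame(followup_years = c(1, 2, 3), event = c(1L, 1L, 1L),
                   x = c(0, 1, 0))
  fit <- fit_cox(d3, "x")
  expect_lt(abs(fit$coefficients[["x"]] -
                  grid_max_beta(d3$followup_years, d3$event, d3$x)), 1e-3)

  # x = (1, 0, 0) is separated (earliest event carries the only 1):
  # the likelihood increases without bound and the fit reports failure
  dsep <- data.frame(followup_years = c(1, 2, 3), event = c(1L, 1L, 1L),
                     x = c(1, 0, 0))
  expect_error(suppressWarnings(fit_cox(dsep, "x")), "converge")

  # random <=5-subject instances with distinct times
  set.seed(301)
  for (i in 1:20) {
    n <- sample(3:5, 1)
    d <- data.frame(followup_years = sample(seq(1, 50, by = 1), n),
                    event = pmin(rbinom(n, 1, 0.8) + c(1, rep(0, n - 1)), 1),
                    x = rbinom(n, 1, 0.5))
    if (length(unique(d$x)) < 2) d$x[1:2] <- c(0, 1)
    beta_grid <- grid_max_beta(d$followup_years, d$event, d$x)
    if (abs(beta_grid) > 4.5) next # separation: likelihood maximized at edge
    fit <- fit_cox(d, "x")
    expect_lt(abs(fit$coefficients[["x"]] - beta_grid), 1e-3)
  }
})

test_that("fit_cox validates its inputs", {
  d <- make_min_cohort(100)
  d$z <- 1
  expect_error(fit_cox(d, "z"), "'z' is constant")
  d$event <- 0L
  expect_error(fit_cox(d, "age"), "no events")
  expect_error(fit_cox(make_min_cohort(50), character()), "at least one")
})

test_that("two-group exponential recovery and the rate-ratio oracle", {
  set.seed(302)
  d <- make_two_group_exp(20000, rate0 = 0.01, hr = 2)
  fit <- fit_cox(d, "x")
  b <- fit$coefficients[["x"]]
  expect_lt(abs(b - log(2)), 0.05)
  # the semiparametric estimate tracks the parametric exponential MLE;
  # the two differ O(1/sqrt(n)), not to 1e-3, at this n
  expect_lt(abs(b - rate_ratio_oracle(d)), 0.01)
})

test_that("affine exposure rescaling rescales beta inversely", {
  set.seed(303)
  n <- 4000
  x <- rnorm(n, 10, 3)
  d <- make_min_cohort(n, lp = 0.1 * (x - 10), baseline = 0.01)
  d$x <- x
  d$x_scaled <- 10 * x + 3
  f1 <- fit_cox(d, c("x", "age"))
  f2 <- fit_cox(d, c("x_scaled", "age"))
  expect_equal(f1$coefficients[["x"]], 10 * f2$coefficients[["x_scaled"]],
               tolerance = 1e-6)
  # per-IQR effect is invariant when the IQR is recomputed on the new scale
  e1 <- effect_per_iqr(f1, "x", IQR(d$x))
  e2 <- effect_per_iqr(f2, "x_scaled", IQR(d$x_scaled))
  expect_equal(e1$hr, e2$hr, tolerance = 1e-6)
})

test_that("effect_per_iqr reproduces hand-worked arithmetic", {
  fit <- structure(list(coefficients = c(x = 0.05),
                        covariance = matrix(0.01^2, 1, 1,
                                            dimnames = list("x", "x"))),
                   class = "cox_fit")
  e <- effect_per_iqr(fit, "x", 2.3)
  expect_equal(e$hr, exp(0.115), tolerance = 1e-10)
  expect_equal(e$ci_low, exp((0.05 - qnorm(0.975) * 0.01) * 2.3),
               tolerance = 1e-10)
  expect_equal(e$ci_high, exp((0.05 + qnorm(0.975) * 0.01) * 2.3),
               tolerance = 1e-10)
  fit0 <- structure(list(coefficients = c(x = 0),
                         covariance = matrix(1e-4, 1, 1,
                                             dimnames = list("x", "x"))),
                    class = "cox_fit")
  expect_equal(effect_per_iqr(fit0, "x", 5)$hr, 1.0)
  expect_error(effect_per_iqr(fit, "x", -1), "positive")
  expect_error(effect_per_iqr(fit, "nope", 1), "not in fit")
})

test_that("95% CIs cover the truth at nominal rate", {
  set.seed(304)
  cover <- replicate(400, {
    d <- make_two_group_exp(1500, rate0 = 0.02, hr = 1.8)
    fit <- fit_cox(d, "x")
    se <- sqrt(fit$covariance["x", "x"])
    b <- fit$coefficients[["x"]]
    abs(b - log(1.8)) < qnorm(0.975) * se
  })
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("quartile contrasts have Q1 = 1 and a powered trend test", {
  set.seed(305)
  n <- 8000
  x <- runif(n)
  d <- make_min_cohort(n, lp = 1.2 * x, baseline = 0.02)
  d$x <- x
  qt <- quartile_and_trend(d, "x", c("age", "sex"))
  expect_equal(qt$estimates$hr[1], 1.0)
  expect_equal(qt$estimates$term, paste0("Q", 1:4))
  # uniform(0,1) cut points near 0.25/0.5/0.75
  expect_lt(max(abs(qt$cuts - c(0.25, 0.5, 0.75))), 0.03)
  # monotone dose-response: trend detected
  expect_lt(qt$p_trend, 0.05)
  expect_gt(qt$estimates$hr[4], qt$estimates$hr[2])
  expect_error(quartile_and_trend(d, "x", "age", cuts = c(0.5, 0.5, 0.7)),
               "tied")
  d$xc <- rep(c(1, 2, 3), length.out = n)
  expect_error(quartile_and_trend(d, "xc", "age"), "4 distinct")
})

test_that("km_logrank separates groups and respects symmetry", {
  set.seed(306)
  d <- make_two_group_exp(5000, rate0 = 0.02, hr = 2)
  km <- km_logrank(d, factor(d$x))
  expect_lt(km$p_logrank, 1e-6)
  # identical duplicated groups: log-rank p = 1
  dd <- rbind(d, d)
  dd$g <- rep(c("a", "b"), each = nrow(d))
  km2 <- km_logrank(dd, "g")
  expect_equal(km2$p_logrank, 1, tolerance = 1e-6)
  # no censoring: KM equals the empirical survival function
  d2 <- data.frame(followup_years = rexp(300, 0.1), event = 1L,
                   g = rep("a", 300))
  sf <- survival::survfit(survival::Surv(followup_years, event) ~ 1,
                          data = d2)
  emp <- sapply(sf$time, function(tt) mean(d2$followup_years > tt))
  expect_equal(sf$surv, emp, tolerance = 1e-10)
  expect_error(km_logrank(d2, "g"), "2 groups")
})

test_that("schoenfeld test holds its size under PH and detects violations", {
  set.seed(307)
  # type I error under proportional hazards (reduced replicates)
  rej <- replicate(300, {
    d <- make_two_group_exp(400, rate0 = 0.05, hr = 1.5, horizon = 10)
    fit <- fit_cox(d, "x")
    schoenfeld_ph_test(fit)$p[1] < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)

  # strongly time-increasing effect: piecewise hazard, null before t0,
  # strong after
  rej_pw <- replicate(60, {
    n <- 1200
    x <- rbinom(n, 1, 0.5)
    t0 <- 3
    # piecewise-exponential draw: rate r1 before t0, r2 after
    r1 <- 0.05
    r2 <- 0.05 * ifelse(x == 1, 6, 1)
    t1 <- rexp(n, r1)
    t2 <- t0 + rexp(n, r2)
    tt <- ifelse(t1 < t0, t1, t2)
    d <- data.frame(followup_years = pmin(tt, 10),
                    event = as.integer(tt <= 10), x = x)
    fit <- fit_cox(d, "x")
    schoenfeld_ph_test(fit)$p[1] < 0.05
  })
  expect_gt(mean(rej_pw), 0.5)
})
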