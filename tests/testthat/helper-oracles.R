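# Independent oracles and small fixture builders used across tests.

# Cox partial log-likelihood for a single covariate, written out directly
# from the definition (distinct event times; Breslow = Efron there).
partial_loglik_1d <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Brute-force grid maximizer of the partial likelihood over beta in [-5, 5].
grid_max_beta <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, partial_loglik_1d, numeric(1), time = time,
               event = event, x = x)
  grid[which.max(ll)]
}

# Two-group exponential cohort with administrative censoring; the
# closed-form rate-ratio oracle log((d1/T1)/(d0/T0)) estimates the log HR.
make_two_group_exp <- function(n, rate0, hr, horizon = 14) {
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate0 * hr^x)
  cens <- runif(n, horizon - 3, horizon)
  data.frame(followup_years = pmin(t_event, cens),
             event = as.integer(t_event <= cens), x = x)
}

rate_ratio_oracle <- function(d) {
  with(d, log((sum(event[x == 1]) / sum(followup_years[x == 1])) /
                (sum(event[x == 0]) / sum(followup_years[x == 0]))))
}

# Minimal cohort slab with the model1 covariate columns plus arbitrary
# extra columns, exponential outcomes driven by a supplied log-hazard lp.
make_min_cohort <- function(n, lp = rep(0, n), baseline = 0.01,
                            horizon = 14, extra = NULL) {
  d <- data.frame(
    age = rnorm(n, 60, 5),
    sex = factor(sample(c("female", "male"), n, TRUE),
                 c("female", "male")))
  if (!is.null(extra)) d <- cbind(d, extra)
  t_event <- rexp(n) / (baseline * exp(lp))
  cens <- runif(n, horizon - 3, horizon)
  d$followup_years <- pmin(t_event, cens)
  d$event <- as.integer(t_event <= cens)
  d
}

# Fast-running generator configuration: small n needs a higher event rate
# than the calibrated 1.5% world for stable fits; structural tests use this.
test_config <- function(n, seed = 1, baseline = 0.004, ...) {
  cohort_config(n_subjects = n, baseline_hazard = baseline, seed = seed, ...)
}

# Zeroed effect configuration (inert score, genetics and covariates).
zero_effects <- function() {
  te <- default_true_effects()
  te$score_per_iqr <- 0
  te$score_quartile[] <- 0
  te$prs_per_unit <- 0
  te$apoe[] <- 0
  te$covariates[] <- 0
  te
}
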