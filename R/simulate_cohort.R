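# Synthetic cohort generator: log-normal pollutant marginals tied by a
# Gaussian copula, Table-1-style covariates, binomial SNP dosages with
# phased APOE haplotypes, and an exponential proportional-hazards event
# process with staggered administrative censoring.

# Solve (meanlog, sdlog) so a log-normal has the requested mean and IQR.
# The ratio IQR/mean = g(s) = (exp(s*z) - exp(-s*z)) * exp(-s^2/2),
# z = qnorm(0.75), rises from 0 to a maximum (~0.90 near s = 1.15) before
# falling again; concentration-like data live on the increasing branch, so
# invert there by uniroot.
lnorm_params <- function(mean, iqr) {
  z <- stats::qnorm(0.75)
  ratio <- iqr / mean
  g <- function(s) (exp(s * z) - exp(-s * z)) * exp(-s^2 / 2)
  opt <- stats::optimize(g, c(1e-8, 4), maximum = TRUE)
  if (ratio >= opt$objective)
    stopf("IQR/mean ratio %.3f is not attainable by a log-normal", ratio)
  s <- stats::uniroot(function(s) g(s) - ratio, c(1e-8, opt$maximum),
                      tol = 1e-12)$root
  c(meanlog = unname(log(mean)) - s^2 / 2, sdlog = s)
}

#' Generate correlated pollutant exposures
#'
#' Draws the four pollutant concentrations from log-normal marginals whose
#' mean and IQR match the configured targets, coupled by a Gaussian copula
#' calibrated so the realized Spearman rank correlations match
#' `config$pollutant_spearman` (Pearson correlation of the latent normals
#' set to `2 * sin(pi * rho_S / 6)`).
#'
#' @param config A [cohort_config()].
#' @param n Number of rows (defaults to `config$n_subjects`).
#' @return Data frame with columns `pm25`, `pm10`, `no2`, `nox` (ug/m3).
#' @export
generate_exposures <- function(config, n = config$n_subjects) {
  rho_s <- config$pollutant_spearman
  rho_p <- 2 * sin(pi * rho_s / 6)
  diag(rho_p) <- 1
  ch <- tryCatch(chol(rho_p), error = function(e)
    stopf("copula correlation matrix is not positive definite: %s",
          conditionMessage(e)))
  z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% ch
  u <- stats::pnorm(z)
  out <- vector("list", 4L)
  for (j in 1:4) {
    par <- lnorm_params(config$pollutant_means[j], config$pollutant_iqrs[j])
    out[[j]] <- stats::qlnorm(u[, j], par["meanlog"], par["sdlog"])
  }
  names(out) <- names(config$pollutant_means)
  as.data.frame(out)
}

#' Generate SNP dosages and phased APOE genotypes
#'
#' SNP dosages are independent Binomial(2, freq) draws per panel entry.
#' APOE genotypes are generated as two phased haplotypes from the
#' epsilon-2/3/4 frequencies and expressed as phased allele pairs at
#' rs429358 and rs7412 (`"C|T"` style, haplotype order aligned across the
#' two sites), so dosage-group proportions follow Hardy-Weinberg
#' expectations.
#'
#' @inheritParams generate_exposures
#' @return Data frame with `snp01 ... snp29` dosage columns, phased
#'   `rs429358`/`rs7412` genotype strings and the generating `apoe_hap1`,
#'   `apoe_hap2` labels.
#' @export
generate_genetics <- function(config, n = config$n_subjects) {
  panel <- config$snp_panel
  G <- sapply(panel$freq, function(f) stats::rbinom(n, 2L, f))
  colnames(G) <- panel$snp_id
  haps <- names(config$apoe_freqs)
  h1 <- sample(haps, n, replace = TRUE, prob = config$apoe_freqs)
  h2 <- sample(haps, n, replace = TRUE, prob = config$apoe_freqs)
  # haplotype -> (rs429358, rs7412): e4 = C-C, e3 = T-C, e2 = T-T
  a429 <- c(e2 = "T", e3 = "T", e4 = "C")
  a7412 <- c(e2 = "T", e3 = "C", e4 = "C")
  out <- as.data.frame(G)
  out$rs429358 <- paste(a429[h1], a429[h2], sep = "|")
  out$rs7412 <- paste(a7412[h1], a7412[h2], sep = "|")
  out$apoe_hap1 <- h1
  out$apoe_hap2 <- h2
  out
}

generate_covariates <- function(config, n = config$n_subjects) {
  cs <- config$covariate_spec
  # truncated-normal age by inverse-cdf sampling
  lo <- stats::pnorm(cs$age_range[1], cs$age_mean, cs$age_sd)
  hi <- stats::pnorm(cs$age_range[2], cs$age_mean, cs$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), cs$age_mean, cs$age_sd)
  rcat <- function(p) factor(sample(names(p), n, TRUE, prob = p / sum(p)),
                             levels = names(p))
  data.frame(
    age = age,
    sex = factor(ifelse(stats::runif(n) < cs$p_male, "male", "female"),
                 levels = c("female", "male")),
    education = factor(ifelse(stats::runif(n) < cs$p_college,
                              "college", "no_college"),
                       levels = c("college", "no_college")),
    income = factor(ifelse(stats::runif(n) < cs$p_income_high,
                           "high", "low"), levels = c("low", "high")),
    smoking = rcat(cs$p_smoking),
    drinking = rcat(cs$p_drinking),
    activity = rcat(cs$p_activity),
    diet = as.integer(as.character(rcat(cs$p_diet))),
    urban = factor(ifelse(stats::runif(n) < cs$p_urban, "urban", "rural"),
                   levels = c("rural", "urban")),
    tdi = stats::rnorm(n, cs$tdi_mean, cs$tdi_sd),
    bmi = stats::rnorm(n, cs$bmi_mean, cs$bmi_sd),
    family_history = factor(ifelse(stats::runif(n) < cs$p_family_history,
                                   "yes", "no"), levels = c("no", "yes"))
  )
}

# True (generating) pollution score: configured per-unit weights applied to
# the exposures, normalized the same way the analysis score is.
true_score <- function(exposures, config) {
  a <- config$true_effects$true_alphas
  as.numeric(as.matrix(exposures[, c("pm25", "pm10", "no2", "nox")]) %*% a) *
    (4 / sum(a))
}

# Linear predictor of the generating hazard model, on the configured
# effects; returned uncentred.
true_linear_predictor <- function(records, config, score, prs) {
  te <- config$true_effects
  lp <- numeric(nrow(records))

  if (te$score_model == "linear") {
    iqr_s <- stats::IQR(score)
    lp <- lp + te$score_per_iqr * score / iqr_s
  } else {
    q <- stats::quantile(score, c(0.25, 0.5, 0.75))
    idx <- findInterval(score, q) # 0..3
    step <- c(0, te$score_quartile)
    lp <- lp + step[idx + 1L]
  }

  if (te$prs_model == "linear") {
    lp <- lp + te$prs_per_unit * prs
  } else {
    qt <- stats::quantile(prs, c(1, 2) / 3)
    idx <- findInterval(prs, qt)
    step <- c(0, te$prs_tertile)
    lp <- lp + step[idx + 1L]
  }

  apoe_dos <- (records$apoe_hap1 == "e4") + (records$apoe_hap2 == "e4")
  lp <- lp + ifelse(apoe_dos == 1, te$apoe["dosage1"],
                    ifelse(apoe_dos == 2, te$apoe["dosage2"], 0))

  if (te$score_x_prs != 0) {
    iqr_s <- stats::IQR(score)
    lp <- lp + te$score_x_prs * (score / iqr_s) * prs
  }

  cv <- te$covariates
  lp <- lp +
    cv["age"] * (records$age - config$covariate_spec$age_mean) +
    cv["sex_male"] * (records$sex == "male") +
    cv["edu_no_college"] * (records$education == "no_college") +
    cv["bmi"] * (records$bmi - config$covariate_spec$bmi_mean) +
    cv["smoking_former"] * (records$smoking == "former") +
    cv["smoking_current"] * (records$smoking == "current") +
    cv["drinking_never"] * (records$drinking == "never") +
    cv["drinking_former"] * (records$drinking == "former") +
    cv["activity_low"] * (records$activity == "low") +
    cv["diet"] * (records$diet - 3) +
    cv["urban"] * (records$urban == "urban") +
    cv["tdi"] * (records$tdi - config$covariate_spec$tdi_mean) +
    cv["family_history"] * (records$family_history == "yes")
  as.numeric(lp)
}

#' Generate survival outcomes under proportional hazards
#'
#' Event times are exponential with rate `baseline_hazard * exp(lp)` where
#' `lp` is the configured linear predictor centred so that
#' `mean(exp(lp)) = 1` (keeping the marginal event rate at the calibrated
#' `baseline_hazard` level regardless of effect sizes). Administrative
#' censoring is uniform on `[admin_end - recruitment_span, admin_end]`
#' (staggered recruitment, fixed end of follow-up) and an
#' `early_censor_frac` fraction is additionally censored uniformly before
#' their horizon. `event = 1` iff the event time precedes censoring.
#'
#' @param records Data frame with exposures, covariates and genetics as
#'   produced by the generator.
#' @param config A [cohort_config()].
#' @param lp Optional precomputed uncentred linear predictor.
#' @return `records` with `followup_years` and `event` columns appended.
#' @export
generate_survival <- function(records, config, lp = NULL) {
  n <- nrow(records)
  if (is.null(lp)) {
    score <- true_score(records, config)
    prs <- as.numeric(as.matrix(records[, config$snp_panel$snp_id]) %*%
                        config$snp_panel$weight)
    lp <- true_linear_predictor(records, config, score, prs)
  }
  lp_c <- lp - log(mean(exp(lp)))
  rate <- config$baseline_hazard * exp(lp_c)
  t_event <- stats::rexp(n) / rate
  horizon <- stats::runif(n, config$admin_end - config$recruitment_span,
                          config$admin_end)
  cens <- horizon
  early <- stats::runif(n) < config$early_censor_frac
  cens[early] <- stats::runif(sum(early), 0, horizon[early])
  records$followup_years <- pmin(t_event, cens)
  records$event <- as.integer(t_event <= cens)
  records
}

#' Simulate a complete synthetic cohort
#'
#' Runs the exposure, covariate, genetics and survival generators in
#' sequence under a single seed. The generating (true) pollution score and
#' PRS are attached as attribute `truth` for validation; the analysis
#' columns themselves contain only what a real cohort table would.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return Data frame, one row per subject, with `id`, exposures,
#'   covariates, SNP dosages, phased APOE genotypes, `followup_years` and
#'   `event`; attribute `truth` holds the generating score, PRS and linear
#'   predictor, attribute `config` the configuration used.
#' @examples
#' cfg <- cohort_config(n_subjects = 500, seed = 7)
#' coh <- simulate_cohort(cfg)
#' summarize_cohort(coh)$event_rate
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  with_seed(seed, {
    ex <- generate_exposures(config)
    cov <- generate_covariates(config)
    gen <- generate_genetics(config)
    records <- cbind(id = seq_len(config$n_subjects), ex, cov, gen)
    if (config$confounding != 0) {
      s <- true_score(records, config)
      records$tdi <- records$tdi +
        config$confounding * (s - mean(s)) / stats::sd(s)
    }
    score <- true_score(records, config)
    prs <- as.numeric(as.matrix(records[, config$snp_panel$snp_id]) %*%
                        config$snp_panel$weight)
    lp <- true_linear_predictor(records, config, score, prs)
    records <- generate_survival(records, config, lp = lp)
    if (anyNA(records)) stopf("generator produced missing values")
    structure(records,
              truth = list(score = score, prs = prs, lp = lp),
              config = config)
  })
}

#' Summarize a cohort table
#'
#' Baseline-characteristics style summary: sample size, events, person
#' years, median follow-up, pollutant means/IQRs, Spearman correlations
#' among pollutants (entries involving a constant column are `NA` with a
#' warning), APOE dosage-group proportions and categorical covariate
#' frequencies.
#'
#' @param records A cohort data frame.
#' @return Named list of summaries.
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stopf("empty cohort")
  poll <- intersect(c("pm25", "pm10", "no2", "nox"), names(records))
  ex <- records[, poll, drop = FALSE]
  sp <- if (nrow(records) >= 3L) spearman_matrix(ex) else {
    warnf("fewer than 3 subjects; rank correlations undefined")
    matrix(NA_real_, length(poll), length(poll),
           dimnames = list(poll, poll))
  }
  cats <- intersect(c("sex", "education", "income", "smoking", "drinking",
                      "activity", "urban", "family_history"), names(records))
  apoe_prop <- NULL
  if (all(c("rs429358", "rs7412") %in% names(records))) {
    ap <- apoe_from_genotypes(records$rs429358, records$rs7412)
    apoe_prop <- prop.table(table(factor(ap$apoe_dosage, levels = 0:2)))
  }
  list(
    n = nrow(records),
    n_events = if ("event" %in% names(records)) sum(records$event) else NA,
    event_rate = if ("event" %in% names(records)) mean(records$event) else NA,
    person_years = if ("followup_years" %in% names(records))
      sum(records$followup_years) else NA,
    median_followup = if ("followup_years" %in% names(records))
      stats::median(records$followup_years) else NA,
    pollutant_means = colMeans(ex),
    pollutant_iqrs = vapply(ex, stats::IQR, numeric(1)),
    spearman = sp,
    apoe_dosage_prop = apoe_prop,
    covariate_props = lapply(records[cats], function(x) prop.table(table(x)))
  )
}

#' Write a cohort to delimited text
#'
#' @param records Cohort data frame.
#' @param path Output file; tab-separated with a single header row.
#' @export
write_cohort <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#' @param path Tab-separated cohort file.
#' @return Data frame with factor covariates restored to their canonical
#'   level order.
#' @export
read_cohort <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  lev <- list(sex = c("female", "male"), education = c("college", "no_college"),
              income = c("low", "high"),
              smoking = c("never", "former", "current"),
              drinking = c("never", "former", "current"),
              activity = c("low", "moderate", "high"),
              urban = c("rural", "urban"), family_history = c("no", "yes"))
  for (nm in intersect(names(lev), names(x)))
    x[[nm]] <- factor(x[[nm]], levels = lev[[nm]])
  x
}
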