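# End-to-end analysis runners: main bundle, subgroup reruns, sensitivity
# variants, with provenance metadata and delimited-text output.

#' Analysis configuration
#'
#' @param covariate_model `"model1"` (age + sex) or `"model2"` (the main
#'   model: model 1 plus education, BMI, drinking, smoking, physical
#'   activity, healthy diet score, urban residency, TDI, family history).
#' @param k_folds Number of cross-validation folds.
#' @param seed Master seed; stage seeds are derived from it.
#' @param subgroups Character vector of stratifier variables for
#'   [run_subgroups()].
#' @param prs_quintile_scheme Use the 20/60/20 PRS quintile regrouping
#'   instead of tertiles (sensitivity).
#' @param drop_followup_lt_2y Exclude subjects followed < 2 years
#'   (sensitivity).
#' @param include_age_lt_50 Keep subjects aged < 50 (the main analysis
#'   restricts to >= 50).
#' @param restrict_age_ge_60 Restrict to subjects aged >= 60.
#' @param extra_covariates Additional covariate column names to adjust
#'   for on top of the model's set.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(covariate_model = "model2", k_folds = 10L,
                            seed = 1L, subgroups = c("sex"),
                            prs_quintile_scheme = FALSE,
                            drop_followup_lt_2y = FALSE,
                            include_age_lt_50 = FALSE,
                            restrict_age_ge_60 = FALSE,
                            extra_covariates = character()) {
  covariate_model <- match.arg(covariate_model, c("model2", "model1"))
  if (include_age_lt_50 && restrict_age_ge_60)
    stopf("contradictory flags: include_age_lt_50 and restrict_age_ge_60")
  if (!is_count(k_folds)) stopf("k_folds must be a positive integer")
  structure(list(covariate_model = covariate_model,
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 subgroups = subgroups,
                 prs_quintile_scheme = prs_quintile_scheme,
                 drop_followup_lt_2y = drop_followup_lt_2y,
                 include_age_lt_50 = include_age_lt_50,
                 restrict_age_ge_60 = restrict_age_ge_60,
                 extra_covariates = extra_covariates),
            class = "analysis_config")
}

apply_population_filters <- function(cohort, config) {
  n0 <- nrow(cohort)
  if (!config$include_age_lt_50) cohort <- cohort[cohort$age >= 50, ]
  if (config$restrict_age_ge_60) cohort <- cohort[cohort$age >= 60, ]
  if (config$drop_followup_lt_2y)
    cohort <- cohort[cohort$followup_years >= 2, ]
  attr(cohort, "n_excluded") <- n0 - nrow(cohort)
  cohort
}

fail_fast_missing <- function(cohort) {
  core <- setdiff(names(cohort), c("apoe_hap1", "apoe_hap2"))
  if (anyNA(cohort[core]))
    stopf("cohort contains missing values; imputation is out of scope")
}

#' Run the main end-to-end analysis
#'
#' Produces the full results bundle on one cohort: per-pollutant per-IQR
#' and quartile hazard ratios with trend and nonlinearity tests (the
#' individual-pollutant table), the cross-validated pollution score
#' analysis with IVW pooling and HMP calibration (the score table),
#' genetic main effects (PRS per unit, APOE dosage groups), the 12-cell
#' joint stratification, and multiplicative/additive interaction
#' statistics. Deterministic given cohort + config.
#'
#' @param cohort Cohort data frame (complete cases; the runner fails fast
#'   on missing values).
#' @param config An [analysis_config()].
#' @param panel PRS panel (defaults to the bundled synthetic panel).
#' @return Object of class `analysis_bundle` with elements `pollutants`,
#'   `score`, `genetics`, `joint`, `interaction`, `meta`.
#' @export
run_main <- function(cohort, config = analysis_config(),
                     panel = default_prs_panel()) {
  fail_fast_missing(cohort)
  cohort <- apply_population_filters(cohort, config)
  covs <- c(covariate_model_terms(config$covariate_model),
            config$extra_covariates)
  cm <- config$covariate_model

  # individual pollutants: per-IQR, quartiles, trend, nonlinearity
  pollutants <- lapply(POLLUTANTS, function(pp) {
    fit <- fit_cox(cohort, c(pp, covs))
    per_iqr <- effect_per_iqr(fit, pp, stats::IQR(cohort[[pp]]))
    qt <- quartile_and_trend(cohort, pp, covs)
    nl <- nonlinearity_test(cohort, pp, covs)
    list(per_iqr = per_iqr, quartiles = qt$estimates, p_trend = qt$p_trend,
         p_nonlinearity = nl$p_nonlinearity)
  })
  names(pollutants) <- POLLUTANTS

  score_res <- run_pollution_score(cohort, cm, k = config$k_folds,
                                   seed = child_seed(config$seed, 1L),
                                   extra_covariates = config$extra_covariates)

  # genetics: PRS (per unit and grouped) and APOE dosage groups
  prs <- compute_prs(cohort[, panel$snp_id], panel)
  scheme <- if (config$prs_quintile_scheme) "quintile_1_234_5" else "tertile"
  prs_grp <- prs_groups(prs, scheme)
  apoe <- apoe_from_genotypes(cohort$rs429358, cohort$rs7412)
  d <- cohort
  d$.prs <- prs
  fit_prs <- fit_cox(d, c(".prs", covs))
  prs_per_unit <- data.frame(
    term = "prs", hr = exp(fit_prs$coefficients[[".prs"]]),
    ci_low = exp(fit_prs$coefficients[[".prs"]] -
                   stats::qnorm(0.975) * sqrt(fit_prs$covariance[".prs", ".prs"])),
    ci_high = exp(fit_prs$coefficients[[".prs"]] +
                    stats::qnorm(0.975) * sqrt(fit_prs$covariance[".prs", ".prs"])),
    p = 2 * stats::pnorm(-abs(fit_prs$coefficients[[".prs"]] /
                                sqrt(fit_prs$covariance[".prs", ".prs"]))),
    scale = "per_unit")
  d$.apoe <- apoe$apoe_group
  keep <- !is.na(d$.apoe)
  fit_apoe <- fit_cox(d[keep, ], c(".apoe", covs))
  idx <- c(".apoeintermediate", ".apoehigh")
  b <- fit_apoe$coefficients[idx]
  se <- sqrt(diag(fit_apoe$covariance)[idx])
  apoe_est <- data.frame(
    term = c("dosage0", "dosage1", "dosage2"),
    hr = c(1, exp(b)),
    ci_low = c(NA, exp(b - stats::qnorm(0.975) * se)),
    ci_high = c(NA, exp(b + stats::qnorm(0.975) * se)),
    p = c(NA, 2 * stats::pnorm(-abs(b / se))), row.names = NULL)

  # joint stratification and interaction on the out-of-fold score
  joint_prs <- joint_strata(cohort, score_res$score, prs_grp, cm,
                            cuts = score_res$cuts)
  mult <- multiplicative_interaction(cohort, score_res$score / score_res$iqr,
                                     prs, cm)
  high_exp <- score_res$score > score_res$cuts[3L]
  addint <- additive_interaction(cohort, high_exp, prs_grp == "high", cm)

  meta <- list(config = config, config_hash = config_hash(config),
               n = nrow(cohort), n_events = sum(cohort$event),
               n_excluded = attr(cohort, "n_excluded"),
               n_apoe_indeterminate = attr(apoe, "n_indeterminate"),
               package_version = as.character(utils::packageVersion("airscore")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  structure(list(pollutants = pollutants, score = score_res,
                 genetics = list(prs_per_unit = prs_per_unit,
                                 apoe = apoe_est, prs_groups = prs_grp,
                                 prs = prs, scheme = scheme),
                 joint = joint_prs,
                 interaction = list(multiplicative = mult,
                                    additive = addint),
                 meta = meta),
            class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat(sprintf("Analysis bundle [%s]: n=%d, events=%d\n",
              x$meta$config_hash, x$meta$n, x$meta$n_events))
  print(x$score)
  g <- x$genetics
  cat(sprintf("  PRS per-unit HR %.3f; APOE e4/e4 HR %.2f\n",
              g$prs_per_unit$hr, g$apoe$hr[3]))
  cat(sprintf("  multiplicative interaction p = %.3g; RERI %.3f, AP %.3f\n",
              x$interaction$multiplicative$p, x$interaction$additive$reri,
              x$interaction$additive$ap))
  invisible(x)
}

#' Re-run the score analysis within subgroups
#'
#' @param cohort Cohort data frame.
#' @param config An [analysis_config()]; `config$subgroups` names the
#'   stratifying variables (each must have >= 2 observed levels;
#'   continuous stratifiers `age`, `bmi`, `tdi`, `diet` are cut at the
#'   conventional thresholds 60, 25/30, the sample mean, and 2.5).
#' @return Named list (one element per stratifier) of per-stratum pooled
#'   score effects; strata without events are skipped with a warning.
#' @export
run_subgroups <- function(cohort, config = analysis_config()) {
  out <- list()
  for (v in config$subgroups) {
    g <- subgroup_levels(cohort, v)
    lev <- levels(g)
    if (length(lev) < 2L) stopf("stratifier '%s' has a single level", v)
    strata <- list()
    for (l in lev) {
      sub <- cohort[!is.na(g) & g == l, , drop = FALSE]
      if (nrow(sub) == 0L || sum(sub$event) == 0L) {
        warnf("subgroup %s=%s has no events; skipped", v, l)
        next
      }
      res <- run_pollution_score(sub, config$covariate_model,
                                 k = config$k_folds,
                                 seed = child_seed(config$seed, 100L))
      strata[[l]] <- list(n = nrow(sub), events = sum(sub$event),
                          pooled = res$pooled)
    }
    out[[v]] <- strata
  }
  out
}

subgroup_levels <- function(cohort, v) {
  if (!v %in% names(cohort)) stopf("unknown stratifier '%s'", v)
  x <- cohort[[v]]
  switch(v,
         age = factor(ifelse(x < 60, "<60", ">=60"), c("<60", ">=60")),
         bmi = cut(x, c(-Inf, 25, 30, Inf), c("<25", "25-30", ">=30")),
         tdi = factor(ifelse(x < mean(x), "low", "high"), c("low", "high")),
         diet = factor(ifelse(x <= 2, "0-2", "3-5"), c("0-2", "3-5")),
         droplevels(as.factor(x)))
}

#' Run the labelled sensitivity variants
#'
#' Each requested flag produces one labelled variant of the pooled score
#' analysis: PRS quintile regrouping, exclusion of follow-up < 2 years,
#' age-range changes, and extra adjustment covariates. Exclusion counts
#' are recorded per variant.
#'
#' @param cohort Cohort data frame.
#' @param config Base [analysis_config()].
#' @param variants Character vector among `"prs_quintiles"`,
#'   `"drop_followup_lt_2y"`, `"include_age_lt_50"`,
#'   `"restrict_age_ge_60"`, `"extra_covariates"`.
#' @param extra_covariates Covariate names for the `"extra_covariates"`
#'   variant.
#' @return Named list of variants, each with the filtered-sample size and
#'   the pooled score effect (plus genetics regrouping where relevant).
#' @export
run_sensitivity <- function(cohort, config = analysis_config(),
                            variants = c("prs_quintiles",
                                         "drop_followup_lt_2y",
                                         "restrict_age_ge_60"),
                            extra_covariates = character()) {
  out <- list()
  for (v in variants) {
    cfg <- config
    if (v == "prs_quintiles") cfg$prs_quintile_scheme <- TRUE
    else if (v == "drop_followup_lt_2y") cfg$drop_followup_lt_2y <- TRUE
    else if (v == "include_age_lt_50") cfg$include_age_lt_50 <- TRUE
    else if (v == "restrict_age_ge_60") cfg$restrict_age_ge_60 <- TRUE
    else if (v == "extra_covariates") cfg$extra_covariates <- extra_covariates
    else stopf("unknown sensitivity variant '%s'", v)
    if (cfg$include_age_lt_50 && cfg$restrict_age_ge_60)
      stopf("contradictory flags: include_age_lt_50 and restrict_age_ge_60")
    sub <- apply_population_filters(cohort, cfg)
    res <- run_pollution_score(sub,
                               cfg$covariate_model, k = cfg$k_folds,
                               seed = child_seed(cfg$seed, 1L),
                               extra_covariates = cfg$extra_covariates)
    item <- list(n = nrow(sub), n_excluded = attr(sub, "n_excluded"),
                 pooled = res$pooled)
    if (v == "prs_quintiles") {
      panel <- default_prs_panel()
      prs <- compute_prs(sub[, panel$snp_id], panel)
      item$prs_groups <- table(prs_groups(prs, "quintile_1_234_5"))
    }
    out[[v]] <- item
  }
  out
}

#' Write an analysis bundle to delimited tables plus a JSON manifest
#'
#' @param bundle A [run_main()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  poll <- do.call(rbind, lapply(names(bundle$pollutants), function(pp) {
    b <- bundle$pollutants[[pp]]
    cbind(pollutant = pp,
          rbind(b$per_iqr[c("term", "hr", "ci_low", "ci_high", "p", "scale")],
                b$quartiles[c("term", "hr", "ci_low", "ci_high", "p", "scale")]))
  }))
  wt(poll, "pollutants.tsv")
  wt(fold_table(bundle$score), "score_folds.tsv")
  sp <- bundle$score$pooled
  wt(data.frame(term = "score_per_iqr", hr = sp$hr, ci_low = sp$ci_low,
                ci_high = sp$ci_high, hmp_raw = sp$hmp_raw,
                p_calibrated = sp$p_calibrated), "score_pooled.tsv")
  wt(bundle$score$quartiles, "score_quartiles.tsv")
  wt(rbind(bundle$genetics$prs_per_unit[c("term", "hr", "ci_low",
                                          "ci_high", "p")],
           bundle$genetics$apoe[c("term", "hr", "ci_low", "ci_high", "p")]),
     "genetics.tsv")
  wt(bundle$joint$strata, "joint_strata.tsv")
  manifest <- list(
    config_hash = bundle$meta$config_hash,
    seed = bundle$meta$config$seed,
    package_version = bundle$meta$package_version,
    n = bundle$meta$n, n_events = bundle$meta$n_events,
    tables = c("pollutants.tsv", "score_folds.tsv", "score_pooled.tsv",
               "score_quartiles.tsv", "genetics.tsv", "joint_strata.tsv"),
    interaction = list(
      multiplicative_p = bundle$interaction$multiplicative$p,
      reri = bundle$interaction$additive$reri,
      reri_ci = bundle$interaction$additive$reri_ci,
      ap = bundle$interaction$additive$ap,
      ap_ci = bundle$interaction$additive$ap_ci))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
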