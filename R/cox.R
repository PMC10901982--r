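# Proportional-hazards estimation and diagnostics (wraps the survival
# package behind the interfaces the score pipeline uses).

#' Covariate sets for the crude and main models
#'
#' Model 1 (crude) adjusts for age and sex only; Model 2 (main) adds
#' education, BMI, drinking status, smoking status, physical activity,
#' healthy diet score, urban residency, TDI and family history of
#' dementia.
#'
#' @param covariate_model `"model1"` or `"model2"`.
#' @return Character vector of covariate column names.
#' @export
covariate_model_terms <- function(covariate_model = c("model2", "model1")) {
  covariate_model <- match.arg(covariate_model)
  m1 <- c("age", "sex")
  if (covariate_model == "model1") return(m1)
  c(m1, "education", "bmi", "drinking", "smoking", "activity", "diet",
    "urban", "tdi", "family_history")
}

check_not_constant <- function(data, vars) {
  for (v in vars) {
    x <- data[[v]]
    if (is.null(x)) stopf("covariate '%s' not found in data", v)
    ux <- unique(x[!is.na(x)])
    if (length(ux) < 2L) stopf("covariate '%s' is constant", v)
  }
}

#' Fit a Cox proportional hazards model
#'
#' Thin wrapper around [survival::coxph()] that validates its inputs
#' (at least one event, no constant covariate), fixes the tie handling,
#' and returns the pieces downstream stages need (coefficients, the
#' inverse-information covariance, log-likelihood and counts).
#'
#' @param data Data frame with follow-up time and event columns.
#' @param covariates Character vector of term names (may include
#'   interaction or transformed terms understood by formulas).
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @param time,event Column names of the outcome.
#' @return Object of class `cox_fit`: list with `coefficients`,
#'   `covariance`, `loglik`, `n`, `n_events`, `tie_method` and the
#'   underlying `model`.
#' @export
fit_cox <- function(data, covariates, tie_method = c("efron", "breslow"),
                    time = "followup_years", event = "event") {
  tie_method <- match.arg(tie_method)
  if (length(covariates) == 0L) stopf("need at least one covariate")
  if (!all(c(time, event) %in% names(data)))
    stopf("data must contain '%s' and '%s'", time, event)
  if (sum(data[[event]]) < 1L) stopf("no events in data")
  plain <- covariates[covariates %in% names(data)]
  check_not_constant(data, plain)
  f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                                paste(covariates, collapse = " + ")))
  # monotone-likelihood warnings for sparse nuisance levels are passed
  # through; true non-convergence is an error
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = tie_method, model = FALSE,
                    x = FALSE, y = TRUE),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("Ran out of iterations|singular", msg))
        stopf("Cox fit failed to converge: %s", msg)
      warnf("Cox fit: %s", sub("\n$", "", msg))
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stopf("Cox fit produced NA coefficients (collinear terms: %s)",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                collapse = ", "))
  structure(list(
    coefficients = stats::coef(fit),
    covariance = stats::vcov(fit),
    loglik = fit$loglik[2L],
    n = fit$n,
    n_events = fit$nevent,
    tie_method = tie_method,
    model = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n=%d, events=%d\n", x$tie_method, x$n,
              x$n_events))
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(coef = x$coefficients, hr = exp(x$coefficients), se = se)
  print(round(tab, 4))
  invisible(x)
}

#' Test the proportional hazards assumption
#'
#' Scaled Schoenfeld residual test (correlation with time) per covariate
#' plus the global test, via [survival::cox.zph()].
#'
#' @param fit A [fit_cox()] object.
#' @param transform Time transform passed to `cox.zph`.
#' @return Data frame with `term`, `chisq`, `df`, `p` (last row `GLOBAL`).
#' @export
schoenfeld_ph_test <- function(fit, transform = "km") {
  if (!inherits(fit, "cox_fit")) stopf("fit must be a cox_fit")
  if (fit$n_events < 1L) stopf("no events in fitted data")
  z <- survival::cox.zph(fit$model, transform = transform)
  tab <- as.data.frame(z$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p = tab$p, row.names = NULL)
}

#' Hazard ratio per IQR increase
#'
#' Rescales a fitted per-unit log-hazard to the per-IQR scale:
#' `HR = exp(beta * iqr)` with Wald 95\% CI
#' `exp((beta +/- 1.96 se) * iqr)`.
#'
#' @param fit A [fit_cox()] object.
#' @param term Coefficient name.
#' @param iqr Interquartile range (positive) on the term's unit scale.
#' @return One-row data frame: `term`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `scale = "per_iqr"`.
#' @export
effect_per_iqr <- function(fit, term, iqr) {
  if (!term %in% names(fit$coefficients))
    stopf("term '%s' not in fit", term)
  if (!is.numeric(iqr) || iqr <= 0) stopf("iqr must be positive")
  b <- fit$coefficients[[term]] * iqr
  se <- sqrt(fit$covariance[term, term]) * iqr
  z <- b / se
  data.frame(term = term, hr = exp(b),
             ci_low = exp(b - stats::qnorm(0.975) * se),
             ci_high = exp(b + stats::qnorm(0.975) * se),
             p = 2 * stats::pnorm(-abs(z)), scale = "per_iqr")
}

#' Quartile contrasts and trend test for an exposure
#'
#' Cuts the exposure at its sample quartiles (Q1 = reference, HR fixed at
#' 1), fits indicator contrasts for Q2-Q4, and computes a trend p-value
#' from a Wald test of the quartile index (integer scores 1-4) entered as
#' a single continuous covariate.
#'
#' @param data Cohort data frame.
#' @param exposure Exposure column name.
#' @param covariates Adjustment covariates.
#' @param cuts Optional externally supplied cut points (length 3).
#' @inheritParams fit_cox
#' @return List: `estimates` (4-row data frame, Q1 first with HR 1),
#'   `p_trend`, `cuts`, and the two underlying fits.
#' @export
quartile_and_trend <- function(data, exposure, covariates, cuts = NULL,
                               time = "followup_years", event = "event") {
  x <- data[[exposure]]
  if (length(unique(x)) < 4L) stopf("need at least 4 distinct exposure values")
  if (is.null(cuts)) cuts <- stats::quantile(x, c(0.25, 0.5, 0.75),
                                             names = FALSE)
  if (any(duplicated(cuts)))
    stopf("tied quartile cut points leave empty quartiles")
  q <- factor(paste0("Q", findInterval(x, cuts, left.open = TRUE) + 1L),
              levels = paste0("Q", 1:4))
  if (any(table(q) == 0L)) stopf("empty exposure quartile")
  d <- data
  d$.quartile <- q
  d$.qindex <- as.integer(q)
  fit_q <- fit_cox(d, c(".quartile", covariates), time = time, event = event)
  fit_t <- fit_cox(d, c(".qindex", covariates), time = time, event = event)
  idx <- paste0(".quartileQ", 2:4)
  b <- fit_q$coefficients[idx]
  se <- sqrt(diag(fit_q$covariance)[idx])
  est <- data.frame(
    term = paste0("Q", 1:4),
    hr = c(1, exp(b)),
    ci_low = c(NA, exp(b - stats::qnorm(0.975) * se)),
    ci_high = c(NA, exp(b + stats::qnorm(0.975) * se)),
    p = c(NA, 2 * stats::pnorm(-abs(b / se))),
    scale = "quartile_vs_Q1", row.names = NULL)
  zt <- fit_t$coefficients[[".qindex"]] /
    sqrt(fit_t$covariance[".qindex", ".qindex"])
  list(estimates = est, p_trend = 2 * stats::pnorm(-abs(zt)), cuts = cuts,
       fit_quartile = fit_q, fit_trend = fit_t)
}

#' Kaplan-Meier curves and log-rank test
#'
#' @param data Cohort data frame.
#' @param group Factor (or column name) defining at least two groups.
#' @inheritParams fit_cox
#' @return List: `survfit` (product-limit curves), `chisq`, `df`,
#'   `p_logrank`.
#' @export
km_logrank <- function(data, group, time = "followup_years",
                       event = "event") {
  g <- if (length(group) == 1L && is.character(group)) data[[group]] else group
  g <- droplevels(as.factor(g))
  if (nlevels(g) < 2L) stopf("need at least 2 groups for the log-rank test")
  if (sum(data[[event]]) < 1L) stopf("no events")
  d <- data.frame(.time = data[[time]], .event = data[[event]], .group = g)
  sf <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = d)
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = d)
  df <- length(sd$n) - 1L
  list(survfit = sf, chisq = sd$chisq, df = df,
       p_logrank = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
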