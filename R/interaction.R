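# Joint score-by-genetics stratification and interaction statistics on the
# multiplicative (product-term HR) and additive (RERI, AP) scales.

#' Twelve-group joint stratification of score quartiles and genetic risk
#'
#' Crosses the air pollution score quartile (Q1-Q4) with a three-level
#' genetic risk group (PRS tertiles or APOE epsilon-4 dosage groups) and
#' fits one Cox model with 11 indicator contrasts against the reference
#' cell (lowest quartile x low genetic risk), adjusted for the chosen
#' covariate set.
#'
#' @param cohort Cohort data frame.
#' @param score Numeric score vector aligned with `cohort` (typically the
#'   out-of-fold score from [run_pollution_score()]).
#' @param genetic_group Factor with 3 levels, low risk first.
#' @param covariate_model `"model1"` or `"model2"`.
#' @param cuts Optional score quartile cut points (default sample
#'   quartiles of `score`).
#' @return List: `strata` (12-row data frame: quartile, genetic group, n,
#'   events, HR with the reference fixed at 1, CI, p) and the underlying
#'   `fit`.
#' @export
joint_strata <- function(cohort, score, genetic_group,
                         covariate_model = "model2", cuts = NULL) {
  if (length(score) != nrow(cohort) ||
      length(genetic_group) != nrow(cohort))
    stopf("score and genetic_group must match the cohort rows")
  g <- droplevels(as.factor(genetic_group))
  if (nlevels(g) != 3L) stopf("genetic_group must have exactly 3 levels")
  if (is.null(cuts)) cuts <- stats::quantile(score, c(0.25, 0.5, 0.75),
                                             names = FALSE)
  q <- factor(paste0("Q", findInterval(score, cuts, left.open = TRUE) + 1L),
              levels = paste0("Q", 1:4))
  cells <- table(q, g)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)
    stopf("empty joint stratum: %s",
          paste(sprintf("%s x %s", rownames(cells)[bad[, 1]],
                        colnames(cells)[bad[, 2]]), collapse = ", "))
  }
  d <- cohort
  d$.cell <- factor(paste(q, g, sep = ":"),
                    levels = as.vector(t(outer(levels(q), levels(g),
                                               paste, sep = ":"))))
  ref_events <- sum(d$event[d$.cell == levels(d$.cell)[1L]])
  if (ref_events < 1L) stopf("reference cell has no events")
  fit <- fit_cox(d, c(".cell", covariate_model_terms(covariate_model)))
  lev <- levels(d$.cell)
  idx <- paste0(".cell", lev[-1L])
  b <- c(0, fit$coefficients[idx])
  se <- c(NA, sqrt(diag(fit$covariance)[idx]))
  ev <- as.vector(t(table(q, g, d$event)[, , "1"]))
  strata <- data.frame(
    quartile = sub(":.*", "", lev),
    genetic_group = sub(".*:", "", lev),
    n = as.vector(t(cells)),
    events = ev,
    hr = exp(b),
    ci_low = exp(b - stats::qnorm(0.975) * se),
    ci_high = exp(b + stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(b / se)), row.names = NULL)
  list(strata = strata, fit = fit, cuts = cuts)
}

#' Multiplicative interaction between score and genetic risk
#'
#' Cox model with both main effects and their product; the exponentiated
#' product-term coefficient measures departure from multiplicativity of
#' the two hazard ratios.
#'
#' @param cohort Cohort data frame.
#' @param score_term,genetic_term Numeric vectors aligned with `cohort`
#'   (e.g. score per IQR and PRS per unit, or binary high/low codings).
#' @param covariate_model `"model1"` or `"model2"`.
#' @return One-row data frame: product-term `hr`, `ci_low`, `ci_high`,
#'   `p`; the `fit` as an attribute.
#' @export
multiplicative_interaction <- function(cohort, score_term, genetic_term,
                                       covariate_model = "model2") {
  if (stats::sd(score_term) == 0 || stats::sd(genetic_term) == 0)
    stopf("interaction terms must vary")
  if (abs(suppressWarnings(stats::cor(score_term, genetic_term))) > 0.999)
    stopf("score and genetic terms are collinear")
  d <- cohort
  d$.s <- score_term
  d$.g <- genetic_term
  d$.sg <- score_term * genetic_term
  fit <- fit_cox(d, c(".s", ".g", ".sg",
                      covariate_model_terms(covariate_model)))
  b <- fit$coefficients[[".sg"]]
  se <- sqrt(fit$covariance[".sg", ".sg"])
  out <- data.frame(term = "score:genetic", hr = exp(b),
                    ci_low = exp(b - stats::qnorm(0.975) * se),
                    ci_high = exp(b + stats::qnorm(0.975) * se),
                    p = 2 * stats::pnorm(-abs(b / se)))
  attr(out, "fit") <- fit
  out
}

# RERI and AP from the three log-hazard coefficients (b1 = high exposure,
# b2 = high genetics, b3 = product) and their covariance, delta-method CIs.
reri_ap_from_coefs <- function(b1, b2, b3, V) {
  hr10 <- exp(b1); hr01 <- exp(b2); hr11 <- exp(b1 + b2 + b3)
  reri <- hr11 - hr10 - hr01 + 1
  ap <- reri / hr11
  g_reri <- c(hr11 - hr10, hr11 - hr01, hr11)
  se_reri <- sqrt(as.numeric(t(g_reri) %*% V %*% g_reri))
  # AP = 1 - exp(-b2-b3) - exp(-b1-b3) + exp(-b1-b2-b3)
  e23 <- exp(-b2 - b3); e13 <- exp(-b1 - b3); e123 <- exp(-b1 - b2 - b3)
  g_ap <- c(e13 - e123, e23 - e123, e13 + e23 - e123)
  se_ap <- sqrt(as.numeric(t(g_ap) %*% V %*% g_ap))
  z <- stats::qnorm(0.975)
  list(reri = reri, reri_ci = c(reri - z * se_reri, reri + z * se_reri),
       reri_se = se_reri,
       ap = ap, ap_ci = c(ap - z * se_ap, ap + z * se_ap), ap_se = se_ap,
       hr10 = hr10, hr01 = hr01, hr11 = hr11)
}

#' Additive interaction: RERI and attributable proportion
#'
#' Dichotomizes exposure and genetic risk (by default: top score quartile
#' vs the rest, and the supplied high-risk indicator), fits a Cox model
#' with the two indicators and their product, and reports the relative
#' excess risk due to interaction `RERI = HR11 - HR10 - HR01 + 1` and the
#' attributable proportion `AP = RERI / HR11`, hazard ratios standing in
#' for risk ratios under a rare outcome. Confidence intervals are by the
#' delta method on the coefficient covariance.
#'
#' @param cohort Cohort data frame.
#' @param high_exposure,high_genetic Logical/0-1 vectors aligned with
#'   `cohort`.
#' @param covariate_model `"model1"` or `"model2"`.
#' @return List with `reri`, `reri_ci`, `ap`, `ap_ci`, the three stratum
#'   HRs and the underlying `fit`.
#' @export
additive_interaction <- function(cohort, high_exposure, high_genetic,
                                 covariate_model = "model2") {
  he <- as.numeric(high_exposure); hg <- as.numeric(high_genetic)
  if (!all(he %in% 0:1) || !all(hg %in% 0:1))
    stopf("high_exposure and high_genetic must be binary")
  d <- cohort
  d$.he <- he
  d$.hg <- hg
  d$.hehg <- he * hg
  fit <- fit_cox(d, c(".he", ".hg", ".hehg",
                      covariate_model_terms(covariate_model)))
  terms <- c(".he", ".hg", ".hehg")
  V <- fit$covariance[terms, terms]
  if (anyNA(V)) stopf("missing coefficient covariance")
  res <- reri_ap_from_coefs(fit$coefficients[[".he"]],
                            fit$coefficients[[".hg"]],
                            fit$coefficients[[".hehg"]], V)
  res$fit <- fit
  res
}
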