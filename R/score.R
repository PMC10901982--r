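# Cross-validated weighted air pollution score: per-pollutant Cox weights
# estimated on training folds, scores computed strictly out of fold,
# held-out association estimates pooled by inverse-variance weighting with
# HMP-calibrated significance.

POLLUTANTS <- c("pm25", "pm10", "no2", "nox")

#' Assign subjects to k cross-validation folds
#'
#' Random balanced partition: fold sizes differ by at most one;
#' deterministic given the seed.
#'
#' @param n Number of subjects (`n >= k`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed (optional).
#' @return Integer vector of fold labels in `1:k`.
#' @export
assign_folds <- function(n, k = 10L, seed = NULL) {
  if (!is_count(n) || !is_count(k)) stopf("n and k must be positive integers")
  if (n < k) stopf("cannot split n=%d subjects into k=%d folds", n, k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Estimate per-pollutant score weights on a training set
#'
#' Each pollutant's weight (alpha) is its log-hazard per unit from a Cox
#' model adjusted for the chosen covariate set. By default the four alphas
#' come from four single-pollutant models: entering the four collinear
#' pollutants jointly produces unstable, sign-flipping estimates, which is
#' the very problem the score construction works around. A joint fit is
#' available behind `joint = TRUE`. The normalizer is
#' `4 / sum(alphas)`; nonpositive weights are retained with a warning
#' unless `floor_negative = TRUE` sets them to zero.
#'
#' @param train Training-fold cohort data.
#' @param covariate_model `"model1"` or `"model2"` (see
#'   [covariate_model_terms()]).
#' @param joint Estimate the four alphas from one joint four-pollutant fit.
#' @param floor_negative Replace negative alphas by zero.
#' @param fold_id Identifier carried through for provenance.
#' @return Object of class `score_weights`: `alphas` (length 4),
#'   `normalizer`, `fold_id`, `covariate_model`.
#' @export
fit_fold_weights <- function(train, covariate_model = "model2",
                             joint = FALSE, floor_negative = FALSE,
                             fold_id = NA_integer_,
                             extra_covariates = character()) {
  covs <- c(covariate_model_terms(covariate_model), extra_covariates)
  if (joint) {
    fit <- fit_cox(train, c(POLLUTANTS, covs))
    alphas <- fit$coefficients[POLLUTANTS]
  } else {
    alphas <- vapply(POLLUTANTS, function(pp) {
      fit <- tryCatch(fit_cox(train, c(pp, covs)), error = function(e)
        stopf("fold %s: %s", fold_id, conditionMessage(e)))
      fit$coefficients[[pp]]
    }, numeric(1))
  }
  if (floor_negative) alphas <- pmax(alphas, 0)
  if (any(alphas <= 0))
    warnf("fold %s: nonpositive pollutant weight(s): %s", fold_id,
          paste(POLLUTANTS[alphas <= 0], collapse = ", "))
  s <- sum(alphas)
  if (s == 0) stopf("fold %s: pollutant weights sum to zero", fold_id)
  if (s < 0)
    warnf("fold %s: pollutant weights sum to %.3g < 0; score sign flips (two-sided inference is unaffected)",
          fold_id, s)
  structure(list(alphas = alphas, normalizer = 4 / s,
                 fold_id = fold_id, covariate_model = covariate_model),
            class = "score_weights")
}

#' Compute the weighted air pollution score
#'
#' `score = (alpha_pm25 * PM2.5 + alpha_pm10 * PM10 + alpha_no2 * NO2 +
#' alpha_nox * NOx) * 4 / sum(alphas)`. Scale-invariant in the weights:
#' multiplying all alphas by c > 0 leaves the score unchanged.
#'
#' @param exposures Data frame or matrix with columns `pm25`, `pm10`,
#'   `no2`, `nox` (or a length-4 vector in that order).
#' @param weights A `score_weights` object from [fit_fold_weights()], or a
#'   plain length-4 numeric vector of alphas.
#' @return Numeric score vector.
#' @examples
#' w <- structure(list(alphas = c(pm25 = 0.02, pm10 = 0.01, no2 = 0.005,
#'                                nox = 0.005), normalizer = 100),
#'                class = "score_weights")
#' compute_score(c(10, 15, 18, 27), w) # 57.5
#' @export
compute_score <- function(exposures, weights) {
  if (is.numeric(weights)) {
    if (length(weights) != 4L) stopf("need 4 pollutant weights")
    weights <- structure(list(alphas = weights,
                              normalizer = 4 / sum(weights)),
                         class = "score_weights")
  }
  a <- weights$alphas
  if (any(!is.finite(a)) || !is.finite(weights$normalizer))
    stopf("non-finite score weights")
  if (is.null(dim(exposures))) exposures <- matrix(exposures, nrow = 1L,
                                                   dimnames = list(NULL, POLLUTANTS))
  if (is.data.frame(exposures)) exposures <- as.matrix(exposures[POLLUTANTS])
  as.numeric(exposures[, POLLUTANTS, drop = FALSE] %*% a) * weights$normalizer
}

#' Held-out-fold association between score and the outcome
#'
#' Fits the per-IQR, quartile-contrast and trend models for the (already
#' computed) out-of-fold score on the test fold only, using the pooled
#' IQR and quartile cut points shared across folds.
#'
#' @param test Test-fold cohort data with a `score` column.
#' @param covariate_model `"model1"` or `"model2"`.
#' @param iqr Score IQR on the pooled out-of-fold scale.
#' @param cuts Pooled quartile cut points (length 3).
#' @param fold_id Identifier for provenance.
#' @return Object of class `fold_result`: per-IQR `beta`, `se`, `p`,
#'   quartile contrasts (`quartile_betas`, `quartile_ses`), trend beta/se,
#'   `n_test`, `events_test`.
#' @export
fold_association <- function(test, covariate_model = "model2", iqr, cuts,
                             fold_id = NA_integer_,
                             extra_covariates = character()) {
  if (sum(test$event) < 1L)
    stopf("fold %s has no events", fold_id)
  covs <- c(covariate_model_terms(covariate_model), extra_covariates)
  fit <- fit_cox(test, c("score", covs))
  b_unit <- fit$coefficients[["score"]]
  se_unit <- sqrt(fit$covariance["score", "score"])
  beta <- b_unit * iqr
  se <- se_unit * iqr

  q <- factor(paste0("Q", findInterval(test$score, cuts, left.open = TRUE) + 1L),
              levels = paste0("Q", 1:4))
  qb <- qse <- rep(NA_real_, 3L)
  names(qb) <- names(qse) <- paste0("Q", 2:4)
  tb <- tse <- NA_real_
  if (all(table(q) > 0L)) {
    d <- test
    d$.quartile <- q
    d$.qindex <- as.integer(q)
    fq <- tryCatch(fit_cox(d, c(".quartile", covs)), error = function(e) NULL)
    if (!is.null(fq)) {
      idx <- paste0(".quartileQ", 2:4)
      qb[] <- fq$coefficients[idx]
      qse[] <- sqrt(diag(fq$covariance)[idx])
    }
    ft <- tryCatch(fit_cox(d, c(".qindex", covs)), error = function(e) NULL)
    if (!is.null(ft)) {
      tb <- ft$coefficients[[".qindex"]]
      tse <- sqrt(ft$covariance[".qindex", ".qindex"])
    }
  }
  structure(list(fold_id = fold_id, beta_per_iqr = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 quartile_betas = qb, quartile_ses = qse,
                 trend_beta = tb, trend_se = tse,
                 n_test = nrow(test), events_test = sum(test$event)),
            class = "fold_result")
}

#' Inverse-variance weighted fixed-effect pooling
#'
#' `beta = sum(w_i b_i) / sum(w_i)` with `w_i = 1 / se_i^2`;
#' `se = 1 / sqrt(sum(w_i))`; HR and Wald 95\% CI by exponentiation.
#'
#' @param betas,ses Per-fold estimates and standard errors (positive);
#'   `NA` pairs are dropped.
#' @return List: `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p_wald`,
#'   `n_folds`.
#' @export
ivw_pool <- function(betas, ses) {
  keep <- is.finite(betas) & is.finite(ses)
  betas <- betas[keep]; ses <- ses[keep]
  if (length(betas) == 0L) stopf("no usable fold estimates to pool")
  if (any(ses <= 0)) stopf("standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  list(beta = beta, se = se, hr = exp(beta),
       ci_low = exp(beta - stats::qnorm(0.975) * se),
       ci_high = exp(beta + stats::qnorm(0.975) * se),
       p_wald = 2 * stats::pnorm(-abs(z)), n_folds = length(betas))
}

#' Spearman rank correlation matrix of the pollutant exposures
#'
#' @param exposures Data frame/matrix of exposure columns (>= 3 rows).
#' @return Symmetric matrix with unit diagonal; entries involving a
#'   constant column are `NA` (flagged with a warning).
#' @export
spearman_matrix <- function(exposures) {
  exposures <- as.data.frame(exposures)
  if (nrow(exposures) < 3L) stopf("need at least 3 subjects")
  const <- vapply(exposures, function(x) length(unique(x)) < 2L, logical(1))
  m <- suppressWarnings(stats::cor(as.matrix(exposures),
                                   method = "spearman"))
  if (any(const)) {
    warnf("constant column(s): %s; correlations undefined",
          paste(names(exposures)[const], collapse = ", "))
    m[const, ] <- NA_real_
    m[, const] <- NA_real_
  }
  diag(m) <- ifelse(const, NA_real_, 1)
  m
}

#' Run the full cross-validated pollution-score analysis
#'
#' The core procedure: (1) randomly split subjects into `k` folds;
#' (2) for each fold, estimate the four per-pollutant Cox weights on the
#' other `k - 1` folds and compute the weighted score on the held-out
#' fold, so no subject's outcome is used to construct their own score;
#' (3) put all out-of-fold scores on one scale (each fold's score is
#' harmonized to unit IQR, which leaves per-IQR and quartile estimands
#' unchanged but keeps a noise-dominated fold's weight normalizer from
#' distorting the shared scale), then compute the pooled score IQR and
#' quartile cut points; (4) estimate the score-outcome association
#' (per IQR, quartile contrasts, trend) within each held-out fold;
#' (5) pool the per-fold estimates by fixed-effect inverse-variance
#' weighting and calibrate the combined p-value with the harmonic mean
#' p-value. Folds without events are skipped with a warning.
#'
#' @param cohort Cohort data frame (exposures, covariates, outcome).
#' @param covariate_model `"model1"` (age + sex) or `"model2"` (main).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param joint_weights,floor_negative Passed to [fit_fold_weights()].
#' @param extra_covariates Additional adjustment covariate names.
#' @return Object of class `pollution_score_result`: `pooled` (per-IQR
#'   pooled effect with `hmp_raw` and `p_calibrated`), `quartiles`
#'   (per-quartile IVW-pooled HRs, Q1 = 1), `p_trend`, `fold_results`,
#'   `fold_weights`, `folds`, out-of-fold `score` (fold-harmonized) and
#'   `score_raw` (literal formula output), `iqr`, `cuts`, `seed`.
#' @export
run_pollution_score <- function(cohort, covariate_model = "model2", k = 10L,
                                seed = NULL, joint_weights = FALSE,
                                floor_negative = FALSE,
                                extra_covariates = character()) {
  n <- nrow(cohort)
  folds <- assign_folds(n, k, seed)
  score <- rep(NA_real_, n)
  weights <- vector("list", k)

  # one shared model matrix + Surv object; per-fold fits run through
  # survival::coxph.fit on row subsets (identical estimates to fit_cox,
  # without per-call formula overhead)
  covs <- c(covariate_model_terms(covariate_model), extra_covariates)
  X0 <- stats::model.matrix(stats::reformulate(covs), cohort)[, -1,
                                                              drop = FALSE]
  y <- survival::Surv(cohort$followup_years, cohort$event)
  E <- as.matrix(cohort[, POLLUTANTS])

  for (f in seq_len(k)) {
    test_idx <- folds == f
    tr <- which(!test_idx)
    if (sum(cohort$event[tr]) < 1L) stopf("fold %d: no training events", f)
    alphas <- if (joint_weights) {
      fit <- cox_fit_fast(cbind(E, X0)[tr, , drop = FALSE], y[tr, ])
      fit$coef[seq_len(4L)]
    } else {
      vapply(seq_len(4L), function(j) {
        fit <- cox_fit_fast(cbind(E[, j, drop = FALSE],
                                  X0)[tr, , drop = FALSE], y[tr, ])
        fit$coef[[1L]]
      }, numeric(1))
    }
    names(alphas) <- POLLUTANTS
    if (floor_negative) alphas <- pmax(alphas, 0)
    if (any(alphas <= 0))
      warnf("fold %d: nonpositive pollutant weight(s): %s", f,
            paste(POLLUTANTS[alphas <= 0], collapse = ", "))
    if (sum(alphas) == 0) stopf("fold %d: pollutant weights sum to zero", f)
    weights[[f]] <- structure(list(alphas = alphas,
                                   normalizer = 4 / sum(alphas),
                                   fold_id = f,
                                   covariate_model = covariate_model),
                              class = "score_weights")
    score[test_idx] <- compute_score(E[test_idx, , drop = FALSE],
                                     weights[[f]])
  }

  # Harmonize fold scales before pooling: the normalizer 4/sum(alphas)
  # only makes out-of-fold scores comparable across folds when the weight
  # sums are stable; at modest n a noise-dominated fold can inflate (or
  # flip) its scale and scramble pooled cut points. Rescaling each fold's
  # score to unit IQR removes that failure mode and leaves every reported
  # quantity (per-IQR effects, quartile contrasts) unchanged, since both
  # are scale-invariant within fold.
  score_raw <- score
  bad_fold <- logical(k)
  for (f in seq_len(k)) {
    idx <- folds == f
    iqr_f <- stats::IQR(score[idx])
    if (!is.finite(iqr_f) || iqr_f <= 0) {
      bad_fold[f] <- TRUE
      warnf("fold %d: degenerate score scale; fold skipped", f)
    } else {
      score[idx] <- score[idx] / iqr_f
    }
  }
  usable <- !bad_fold[folds]
  iqr <- stats::IQR(score[usable])
  cuts <- stats::quantile(score[usable], c(0.25, 0.5, 0.75), names = FALSE)

  fold_results <- vector("list", k)
  for (f in seq_len(k)) {
    if (bad_fold[f]) next
    fold_results[[f]] <- tryCatch(
      fold_association_fast(f, which(folds == f), score, y, X0, iqr, cuts),
      error = function(e) {
        warnf("fold %d skipped: %s", f, conditionMessage(e))
        NULL
      })
  }
  used <- !vapply(fold_results, is.null, logical(1))
  if (!any(used)) stopf("all folds were skipped")
  fr <- fold_results[used]

  betas <- vapply(fr, `[[`, numeric(1), "beta_per_iqr")
  ses <- vapply(fr, `[[`, numeric(1), "se")
  pooled <- ivw_pool(betas, ses)
  hmp <- hmp_combine(vapply(fr, `[[`, numeric(1), "p"))
  pooled$hmp_raw <- hmp$hmp_raw
  pooled$p_calibrated <- hmp$p_calibrated

  napool <- list(beta = NA_real_, se = NA_real_, hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, p_wald = NA_real_,
                 n_folds = 0L)
  qpool <- lapply(paste0("Q", 2:4), function(qn) {
    tryCatch(
      ivw_pool(vapply(fr, function(r) r$quartile_betas[[qn]], numeric(1)),
               vapply(fr, function(r) r$quartile_ses[[qn]], numeric(1))),
      error = function(e) napool)
  })
  quartiles <- data.frame(
    term = paste0("Q", 1:4),
    hr = c(1, vapply(qpool, `[[`, numeric(1), "hr")),
    ci_low = c(NA, vapply(qpool, `[[`, numeric(1), "ci_low")),
    ci_high = c(NA, vapply(qpool, `[[`, numeric(1), "ci_high")),
    p = c(NA, vapply(qpool, `[[`, numeric(1), "p_wald")),
    scale = "quartile_vs_Q1", row.names = NULL)

  tpool <- tryCatch(
    ivw_pool(vapply(fr, `[[`, numeric(1), "trend_beta"),
             vapply(fr, `[[`, numeric(1), "trend_se")),
    error = function(e) napool)

  structure(list(pooled = pooled, quartiles = quartiles,
                 p_trend = tpool$p_wald, trend = tpool,
                 fold_results = fold_results, fold_weights = weights,
                 folds = folds, score = score, score_raw = score_raw,
                 iqr = iqr, cuts = cuts,
                 covariate_model = covariate_model, k = k, seed = seed),
            class = "pollution_score_result")
}

#' @export
print.pollution_score_result <- function(x, ...) {
  cat(sprintf("Cross-validated air pollution score (%s, %d folds)\n",
              x$covariate_model, x$k))
  with(x$pooled, cat(sprintf(
    "  per-IQR HR %.3f (95%% CI %.3f-%.3f), HMP %.3g (calibrated %.3g)\n",
    hr, ci_low, ci_high, hmp_raw, p_calibrated)))
  q <- x$quartiles
  cat(sprintf("  quartiles: %s; p_trend = %.3g\n",
              paste(sprintf("%s %.2f", q$term, q$hr), collapse = ", "),
              x$p_trend))
  invisible(x)
}

#' Tidy per-fold estimates from a pollution score run
#'
#' @param result A [run_pollution_score()] result.
#' @return Data frame with one row per usable fold: fold id, per-IQR beta,
#'   se, p, HR, test-fold size and events.
#' @export
fold_table <- function(result) {
  fr <- Filter(Negate(is.null), result$fold_results)
  data.frame(
    fold = vapply(fr, `[[`, integer(1), "fold_id"),
    beta_per_iqr = vapply(fr, `[[`, numeric(1), "beta_per_iqr"),
    se = vapply(fr, `[[`, numeric(1), "se"),
    p = vapply(fr, `[[`, numeric(1), "p"),
    hr = exp(vapply(fr, `[[`, numeric(1), "beta_per_iqr")),
    n_test = vapply(fr, `[[`, integer(1), "n_test"),
    events_test = vapply(fr, `[[`, integer(1), "events_test"))
}


# Internal: minimal Efron-ties Cox fit on a precomputed design matrix via
# survival::coxph.fit. Estimates agree with fit_cox to machine precision
# (asserted in the test suite); no formula/model.frame overhead.
cox_fit_fast <- function(X, y) {
  fit <- survival::coxph.fit(X, y, strata = NULL, offset = NULL,
                             init = NULL, control = survival::coxph.control(),
                             weights = NULL, method = "efron",
                             rownames = NULL)
  if (is.character(fit)) stopf("Cox fit failed: %s", fit)
  list(coef = fit$coefficients, var = fit$var, loglik = fit$loglik[2L])
}

# Internal fast-path equivalent of fold_association() working on the shared
# design matrix; first column of each fit is the term of interest.
fold_association_fast <- function(fold_id, idx, score, y, X0, iqr, cuts) {
  ev <- y[idx, 2L]
  if (sum(ev) < 1L) stopf("fold %s has no events", fold_id)
  s <- score[idx]
  if (stats::sd(s) == 0) stopf("score constant in fold %s", fold_id)
  Xf <- X0[idx, , drop = FALSE]
  yf <- y[idx, ]
  fit <- cox_fit_fast(cbind(score = s, Xf), yf)
  if (!is.finite(fit$coef[[1L]])) stopf("fold %s: score fit failed", fold_id)
  beta <- fit$coef[[1L]] * iqr
  se <- sqrt(fit$var[1L, 1L]) * iqr

  qi <- findInterval(s, cuts, left.open = TRUE) + 1L
  qb <- qse <- rep(NA_real_, 3L)
  names(qb) <- names(qse) <- paste0("Q", 2:4)
  tb <- tse <- NA_real_
  if (all(tabulate(qi, 4L) > 0L)) {
    Qind <- cbind(Q2 = as.numeric(qi == 2L), Q3 = as.numeric(qi == 3L),
                  Q4 = as.numeric(qi == 4L))
    fq <- tryCatch(cox_fit_fast(cbind(Qind, Xf), yf),
                   error = function(e) NULL)
    if (!is.null(fq) && all(is.finite(fq$coef[1:3]))) {
      qb[] <- fq$coef[1:3]
      qse[] <- sqrt(diag(fq$var)[1:3])
    }
    ft <- tryCatch(cox_fit_fast(cbind(qindex = qi, Xf), yf),
                   error = function(e) NULL)
    if (!is.null(ft) && is.finite(ft$coef[[1L]])) {
      tb <- ft$coef[[1L]]
      tse <- sqrt(ft$var[1L, 1L])
    }
  }
  structure(list(fold_id = fold_id, beta_per_iqr = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 quartile_betas = qb, quartile_ses = qse,
                 trend_beta = tb, trend_se = tse,
                 n_test = length(idx), events_test = as.integer(sum(ev))),
            class = "fold_result")
}
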