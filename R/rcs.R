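# Restricted cubic splines and the nonlinearity likelihood-ratio test.

#' Default restricted cubic spline knots
#'
#' Knots at standard sample quantiles: (10, 50, 90)\% for 3 knots,
#' (5, 35, 65, 95)\% for 4, (5, 27.5, 50, 72.5, 95)\% for 5.
#'
#' @param x Numeric vector.
#' @param n_knots Number of knots (3-5).
#' @return Strictly increasing knot locations.
#' @export
rcs_knots <- function(x, n_knots = 3L) {
  probs <- switch(as.character(n_knots),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stopf("n_knots must be 3, 4 or 5"))
  k <- stats::quantile(x, probs, names = FALSE)
  if (any(diff(k) <= 0)) stopf("degenerate knots (tied quantiles)")
  k
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline (natural spline) basis: the
#' linear term plus `k - 2` nonlinear terms, constrained to be linear
#' beyond the boundary knots. For knots `t_1 < ... < t_k` the j-th
#' nonlinear column is
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'   + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2,}
#' zero for any `x` at or below the first knot.
#'
#' @param x Numeric vector (at least 3 distinct values).
#' @param knots Strictly increasing knot locations (default
#'   [rcs_knots()] with 3 knots).
#' @return Matrix with `length(knots) - 1` columns (`x`, `x1`, ...).
#' @export
rcs_basis <- function(x, knots = rcs_knots(x)) {
  if (length(unique(x)) < 3L) stopf("need at least 3 distinct x values")
  if (length(knots) < 3L || any(diff(knots) <= 0))
    stopf("knots must be at least 3 strictly increasing values")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1L]
  norm <- (tk - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  nl <- sapply(seq_len(k - 2L), function(j) {
    tj <- knots[j]
    (pos3(x - tj) - pos3(x - tk1) * (tk - tj) / (tk - tk1) +
       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  })
  out <- cbind(x, nl)
  colnames(out) <- c("x", paste0("x", seq_len(k - 2L)))
  out
}

#' Likelihood-ratio test for nonlinearity of an exposure-response curve
#'
#' Compares a Cox model with the full restricted-cubic-spline expansion of
#' the exposure against the linear-only model; under linearity the LR
#' statistic is chi-squared with `n_knots - 2` degrees of freedom.
#'
#' @param data Cohort data frame.
#' @param exposure Exposure column name.
#' @param covariates Adjustment covariate names.
#' @param n_knots Number of spline knots (default 3).
#' @param knots Optional explicit knot locations.
#' @inheritParams fit_cox
#' @return List: `p_nonlinearity`, `lr_chisq`, `df`, `knots`, and the two
#'   fits.
#' @export
nonlinearity_test <- function(data, exposure, covariates, n_knots = 3L,
                              knots = NULL, time = "followup_years",
                              event = "event") {
  x <- data[[exposure]]
  if (is.null(x)) stopf("exposure '%s' not found", exposure)
  if (is.null(knots)) knots <- rcs_knots(x, n_knots)
  B <- rcs_basis(x, knots)
  nl_cols <- colnames(B)[-1L]
  if (all(abs(B[, nl_cols]) < 1e-12))
    stopf("spline columns are all zero (degenerate knots)")
  d <- data
  d$.rcs_lin <- B[, 1L]
  for (j in nl_cols) d[[paste0(".rcs_", j)]] <- B[, j]
  spline_terms <- c(".rcs_lin", paste0(".rcs_", nl_cols))
  fit_full <- fit_cox(d, c(spline_terms, covariates), time = time,
                      event = event)
  fit_lin <- fit_cox(d, c(".rcs_lin", covariates), time = time, event = event)
  lr <- 2 * (fit_full$loglik - fit_lin$loglik)
  df <- length(nl_cols)
  list(p_nonlinearity = stats::pchisq(lr, df, lower.tail = FALSE),
       lr_chisq = lr, df = df, knots = knots,
       fit_spline = fit_full, fit_linear = fit_lin)
}
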