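---
title: "Cross-validated multi-pollutant scores: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated multi-pollutant scores: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the weighted air-pollution score and why it is built by
cross-validation, the pooling and calibration of fold estimates, the
genetic-risk constructions, the interaction measures, the synthetic cohort
the tests rely on, and the numerical and design choices that were
genuinely open.

## 1. The problem and the score

Ambient PM~2.5~, PM~10~, NO~2~ and NO~x~ are emitted by overlapping
sources and are strongly rank-correlated (pairwise Spearman 0.67–0.95 in
the package defaults). A Cox model containing all four therefore exhibits
classic collinearity pathology: individually "significant" pollutants
acquire mutually cancelling coefficients of arbitrary sign. The joint
effect is instead summarized by one exposure index,

$$\text{score}_i \;=\; \Big(\hat\alpha_1 \mathrm{PM}_{2.5,i} +
\hat\alpha_2 \mathrm{PM}_{10,i} + \hat\alpha_3 \mathrm{NO}_{2,i} +
\hat\alpha_4 \mathrm{NO}_{x,i}\Big)\cdot \frac{4}{\sum_j \hat\alpha_j},$$

where each $\hat\alpha_j$ is the per-unit log-hazard of pollutant $j$
from its own covariate-adjusted Cox model. The normalizer
$4/\sum\hat\alpha$ makes the score behave like a weighted mean of the
four concentrations (×4), i.e. it stays on a concentration-like scale,
and makes the score invariant to rescaling all weights by a common
factor.

**Why single-pollutant weight models.** Whether the four weights should
come from one joint fit or four single-pollutant fits is not dictated by
the formula. The joint fit is exactly the collinear regression the score
is meant to avoid, so the package defaults to four adjusted
single-pollutant fits per training set; `joint = TRUE` provides the
other reading.

**Why cross-validation.** If the same subjects provide both the weights
and the score–outcome association, the association test is biased
anti-conservative (data reuse: the weights were chosen to predict these
very outcomes). `run_pollution_score()` therefore splits subjects into
$k = 10$ random folds of near-equal size, estimates weights on the
training nine-tenths, computes scores only for the held-out tenth, and
estimates the association within each held-out fold. No subject's
outcome ever touches their own score's weights; a test asserts this by
re-deriving fold weights from the training subjects alone.

## 2. Pooling and calibration

Per-fold estimates $(\hat\beta_i, \mathrm{se}_i)$ of the log-HR per IQR
are combined by fixed-effect inverse-variance weighting,
$\hat\beta = \sum w_i\hat\beta_i / \sum w_i$, $w_i = \mathrm{se}_i^{-2}$,
$\mathrm{se} = (\sum w_i)^{-1/2}$. Folds are exchangeable draws from one
population, so a fixed-effect model is correct by construction;
random-effects pooling would only add noise.

The ten fold p-values are dependent in complicated ways (shared training
data). The harmonic mean p-value,
$\mathring p = (\sum w_i)/(\sum w_i/p_i)$, is robust to positive
dependence, but the harmonic mean of uniforms is not uniform, so
significance uses the asymptotically exact calibration: under the global
null $R = \sum w_i/p_i$ converges (for $\sum w_i = 1$) to the
$\alpha = 1,\ \beta = 1$ stable ("Landau") law with location
$\log L + 1 - \gamma$ and scale $\pi/2$; the calibrated p-value is
$P(R \ge 1/\mathring p)$. The package evaluates that tail by Gil–Pelaez
inversion of the characteristic function,

$$P(R > x) = \tfrac12 + \tfrac1\pi \int_0^\infty
e^{-\pi u/2}\,\frac{\sin\!\big(u(\delta - x) - u\log u\big)}{u}\,du ,$$

with $\delta = \log L + 1 - \gamma$, switching to the regular tail
expansion $1/x$ for $x \ge 10^4$ where the integrand oscillates too fast
for quadrature (the two branches differ by <0.3 % at the seam, shrinking
further out). A test compares this tail with a 40,000-replicate
simulation oracle, and a property test checks monotonicity of the
calibrated p in the raw HMP. With a single p-value the calibration is the
identity.

## 3. Fold-scale harmonization (a deliberate deviation)

The normalizer $4/\sum\hat\alpha$ puts all folds on one scale **only
when the weight sums are stable**. At $n = 50{,}000$ (about 675 training
events per fold) in weak-marginal regimes — e.g. a purely quartile-step
dose–response — $\sum\hat\alpha$ can approach zero or flip sign in
individual folds, inflating that fold's score scale by one to two orders
of magnitude. Pooled quartile cut points computed on such a mixture are
meaningless, and inverse-variance weights become incomparable.

Since every quantity the pipeline reports (log-HR per IQR, quartile
contrasts, trend) is invariant to a positive rescaling of the score
*within a fold*, the pipeline rescales each fold's out-of-fold score to
unit IQR before pooling cut points and fitting the per-fold models. In
well-behaved folds this changes nothing (it divides by a nearly common
constant); in pathological folds it removes the failure mode. The raw,
literal-formula scores are kept in `score_raw`. Folds whose score is
degenerate (zero IQR) are skipped with a warning, as are folds without
events; pooling proceeds on the usable folds and errors only when none
remain.

A related decision: a fold with $\sum\hat\alpha < 0$ is *flagged*, not
rejected. When all four weights go negative the formula self-corrects
(negative over negative), and a mixed-sign fold near zero carries no
signal; its association estimate is approximately null and two-sided
inference is unaffected. Flooring negative weights at zero is available
(`floor_negative = TRUE`) but not default: it biases weights upward and
is unnecessary once scales are harmonized.

## 4. Survival machinery

Cox models use Efron tie handling (the generator produces continuous
times, so ties are incidental); `fit_cox` validates inputs (events
present, no constant covariate), treats monotone-likelihood warnings for
sparse nuisance levels as warnings, and errors on genuine
non-convergence. The proportional-hazards assumption is checked with
scaled Schoenfeld residuals (`cox.zph`). Effects are reported per IQR
($\mathrm{HR} = e^{\beta\cdot\mathrm{IQR}}$, IQR computed on the full
analytic sample, not per fold) and as quartile contrasts with Q1 fixed
at 1; the trend test enters the quartile index 1–4 as a single
continuous covariate (integer scores; quartile medians would be the main
alternative, and with near-symmetric score distributions the two differ
negligibly).

Dose–response shape uses a restricted cubic spline with 3 knots at the
10th/50th/90th percentiles (the conventional default; placement is
otherwise arbitrary at 3 knots). The basis is the truncated-power form,
normalized by the squared boundary-knot span, linear beyond the boundary
knots — asserted by finite differences in the tests. Nonlinearity is a
likelihood-ratio test of spline vs linear-only models
($\chi^2$, knots − 2 df).

## 5. Genetics

The polygenic risk score is the exact weighted dosage sum
$\mathrm{PRS}_i = \sum_{j=1}^{29} G_{ij}\hat\beta_j$ over a 29-SNP,
APOE-free panel. The bundled panel is **synthetic** (the real SNP list
and GWAS weights are not redistributable); frequencies and weights are
chosen so the PRS standard deviation is close to 1, making the per-unit
effect read approximately per SD. A real panel can be supplied as TSV
(`read_prs_panel`). Risk groups are PRS tertiles (default) or the
20/60/20 quintile regrouping used for sensitivity analysis; ties at a
cut go to the lower group, deterministically, with a warning.

*APOE* status is derived from rs429358/rs7412: ε4 = (C, C), ε3 = (T, C),
ε2 = (T, T); dosage = number of ε4 haplotypes; groups low/intermediate/
high for dosage 0/1/2. Unphased double heterozygotes (C/T at both sites)
are genuinely ambiguous (ε2/ε4 vs ε1/ε3) and are excluded with a count
rather than imputed — there is no principled resolution rule, and at
realistic frequencies they are ~0.5 % of subjects. The generator emits
phased haplotypes, so on simulated data the mapping inverts the
generator exactly (tested).

## 6. Interaction

The 12-group analysis crosses score quartiles with a 3-level genetic
group in one Cox model with 11 indicators (reference: lowest quartile ×
low genetic risk); empty cells are an error naming the cell.
Multiplicative interaction is the exponentiated product-term
coefficient. Additive interaction dichotomizes both factors — default:
top score quartile vs rest, and high genetic group (or any supplied
indicator) vs rest — and reports
$\mathrm{RERI} = \mathrm{HR}_{11} - \mathrm{HR}_{10} -
\mathrm{HR}_{01} + 1$ and $\mathrm{AP} = \mathrm{RERI}/\mathrm{HR}_{11}$
with delta-method CIs from analytic gradients; hazard ratios stand in
for risk ratios, defensible at the ~1.5 % event rate. The 2×2 collapse
is configurable since no standard choice exists.

## 7. The synthetic cohort: what it emulates, and what it does not

The generator draws, in order: exposures, covariates, genetics, and
survival, all under one seed (bit-identical replay is tested).

* **Exposures.** Log-normal marginals (nonnegative, right-skewed, the
  standard model for concentrations) with mean/IQR inverted numerically
  to (µ, σ) — defaults 9.9 (2.3), 14.8 (3.2), 18.1 (6.9), 26.9 (12.0)
  µg/m³ — coupled by a Gaussian copula with the Pearson latent
  correlation $2\sin(\pi\rho_S/6)$ matched to the target Spearman
  matrix (defaults 0.67–0.95, strongest within the particulate and
  NO~2~/NO~x~ pairs).
* **Covariates.** Age truncated-normal 59.9 (5.4) on [50, 70); category
  mixes for sex, education, income, smoking, drinking, activity, diet,
  urbanicity, family history; TDI and BMI normal. Covariates are
  independent of exposures by default; a `confounding` knob adds a
  TDI–exposure link so tests can verify that adjustment matters.
* **Genetics.** SNP dosages Binomial(2, f) per panel entry; APOE as two
  phased haplotypes with ε2/ε3/ε4 = 0.08/0.78/0.14, giving
  Hardy–Weinberg dosage-group shares ≈ 74/24/2 % (the reference shares
  normalized over observed categories; the raw printed shares are not
  Hardy–Weinberg-consistent for any single frequency).
* **Survival.** Exponential event times with rate
  $h_0 e^{\mathrm{lp}}$, where the linear predictor (score effect,
  genetic effects, covariate effects, optional score×PRS product) is
  centred so $E[e^{\mathrm{lp}}] = 1$ — the marginal event rate then
  tracks $h_0$ (default 0.00113/yr) regardless of effect sizes.
  Administrative censoring is uniform on [12.0, 14.8] years (staggered
  recruitment with a fixed end of follow-up: median 13.4 y), plus 3 %
  uniform early censoring standing in for death/loss to follow-up —
  the split between death and loss to follow-up is not separately
  modelled, so this is a stand-in, not an inference.

Default true effects are the reference values the pipeline is
expected to recover: score HR 1.13 per IQR (or quartile steps
1.12/1.19/1.26), PRS HR 1.25 per unit, APOE ε4 HRs 3.0/8.64, plus
modest lifestyle effects. The "true score" driving the hazard uses fixed
per-unit weights derived from the reference single-pollutant per-IQR
estimates; the pipeline re-estimates weights from data, and the
out-of-fold score correlates ≈ 0.99 with the true score at n = 50,000,
so recovery attenuation is below 1 % for the linear effect and a few
percent for quartile contrasts (quartile misclassification).

**What a green recovery test does not establish:** the generator has no
spatial exposure structure, no time-varying exposures, no missing data,
no population stratification (hence no genetic principal components),
no competing risks, and exposure–covariate confounding only via the
explicit knob. Recovery on this world validates the estimation
machinery, not the epidemiology of any real cohort.

## 8. Numerical choices and degenerate inputs

* Log-normal (µ, σ) from mean/IQR by root-finding on the increasing
  branch of IQR/mean as a function of σ; ratios beyond the attainable
  maximum (≈ 0.887) are rejected with a message.
* Landau tail: quadrature below $x = 10^4$, $1/x$ beyond; calibrated p
  clamped to $[\mathring p, 1]$ (the calibrated value can never
  undercut the raw harmonic mean).
* Quantile cuts use the default sample-quantile definition; values
  equal to a cut fall to the lower group everywhere (folds, quartiles,
  PRS groups), making group labels permutation-equivariant.
* Degenerate inputs error early with named culprits: constant
  covariates, empty joint cells, tied quartile cuts, knots outside the
  data, dosages outside {0, 1, 2}, non-positive-definite copula
  matrices.
* Seeds: every stochastic stage takes an explicit seed; runners derive
  stage seeds from one master seed; all derived seeds stay below
  $2^{31}$.

## 9. Known limitations

* The HMP calibration is asymptotic in L and exact only under the
  global null; with L = 10 its finite-L error is visible (~5 % relative
  at moderate tails) but conservative in the direction of the raw HMP
  bound.
* Fold-level weight instability is handled (harmonization, flags), but
  in a truly null-score world the score itself is noise; quartile
  contrasts then estimate nothing and are reported as such (wide CIs,
  occasional skipped folds) rather than suppressed.
* RERI/AP inherit the rare-outcome HR≈RR approximation; at event rates
  far above a few percent the additive-scale reading degrades.
* The subgroup and sensitivity runners reproduce the *procedure* of the
  corresponding cohort analyses; real-data values are not reproducible
  without access-restricted cohort data, and no attempt is made to
  fake them.
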