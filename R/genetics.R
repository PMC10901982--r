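# Polygenic risk score and APOE epsilon-4 dosage grouping.

#' Bundled synthetic 29-SNP PRS panel
#'
#' The dementia PRS is a weighted sum of risk-allele dosages over 29
#' APOE-free SNPs. The real panel (SNP identities and GWAS weights) is not
#' redistributable, so the package bundles a synthetic stand-in with
#' plausible allele frequencies and per-allele log-hazard weights (PRS SD
#' close to 1, so a per-unit effect reads approximately per SD). Supply a
#' real panel with [read_prs_panel()] for applied use.
#'
#' @return Data frame with columns `snp_id`, `risk_allele`, `freq`,
#'   `weight` (29 rows).
#' @export
default_prs_panel <- function() {
  path <- system.file("extdata", "prs_panel_synthetic.tsv",
                      package = "airscore")
  if (path == "") # during development before installation
    path <- file.path("inst", "extdata", "prs_panel_synthetic.tsv")
  read_prs_panel(path)
}

#' Read a PRS panel from tab-separated text
#'
#' @param path File with columns `snp_id`, `risk_allele`, `weight` and
#'   optionally `freq` (needed only for simulation).
#' @return Validated panel data frame.
#' @export
read_prs_panel <- function(path) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "risk_allele", "weight")
  if (!all(need %in% names(panel)))
    stopf("PRS panel must have columns %s", paste(need, collapse = ", "))
  if (nrow(panel) != 29L)
    stopf("PRS panel must have exactly 29 SNPs, got %d", nrow(panel))
  if (any(!is.finite(panel$weight))) stopf("panel weights must be finite")
  if (anyDuplicated(panel$snp_id)) stopf("duplicated snp_id in panel")
  panel
}

#' Compute the polygenic risk score
#'
#' `PRS = sum_j G_j * beta_j` over the 29 panel SNPs, where `G_j` is the
#' risk-allele dosage in \{0, 1, 2\} and `beta_j` the panel weight.
#'
#' @param dosages Numeric vector of length 29, or an n x 29 matrix / data
#'   frame with columns in panel order (matched by name when available).
#' @param panel A PRS panel (see [default_prs_panel()]).
#' @return Numeric vector of PRS values (scalar for a single subject).
#' @examples
#' panel <- default_prs_panel()
#' compute_prs(rep(0, 29), panel) # 0
#' @export
compute_prs <- function(dosages, panel = default_prs_panel()) {
  if (is.data.frame(dosages)) dosages <- as.matrix(dosages)
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1L)
  if (ncol(dosages) != nrow(panel))
    stopf("dosage vector length %d does not match panel size %d",
          ncol(dosages), nrow(panel))
  if (!is.null(colnames(dosages)) && all(panel$snp_id %in% colnames(dosages)))
    dosages <- dosages[, panel$snp_id, drop = FALSE]
  if (anyNA(dosages) || any(!dosages %in% c(0, 1, 2)))
    stopf("dosages must all lie in {0, 1, 2}")
  as.numeric(dosages %*% panel$weight)
}

#' Group subjects by PRS quantiles
#'
#' Two grouping schemes: `"tertile"` gives low/moderate/high thirds;
#' `"quintile_1_234_5"` gives low = 1st quintile, moderate = 2nd-4th,
#' high = 5th (a 20/60/20 split used for sensitivity analysis). Cut points
#' are sample quantiles; values equal to a cut point fall in the lower
#' group (deterministic tie-break); a warning is emitted when ties sit on
#' a boundary.
#'
#' @param prs Numeric vector of PRS values (at least 3 distinct).
#' @param scheme Grouping scheme.
#' @return Factor with levels `low`, `moderate`, `high`, same order as
#'   input (permutation-equivariant).
#' @export
prs_groups <- function(prs, scheme = c("tertile", "quintile_1_234_5")) {
  scheme <- match.arg(scheme)
  if (length(unique(prs)) < 3L) stopf("need at least 3 distinct PRS values")
  probs <- if (scheme == "tertile") c(1, 2) / 3 else c(0.2, 0.8)
  cuts <- stats::quantile(prs, probs, names = FALSE)
  if (any(duplicated(cuts)) ||
      any(vapply(cuts, function(ct) sum(prs == ct) > 1, logical(1))))
    warnf("ties at a quantile boundary; ties assigned to the lower group")
  idx <- findInterval(prs, cuts, left.open = TRUE) # value == cut -> lower
  factor(c("low", "moderate", "high")[idx + 1L],
         levels = c("low", "moderate", "high"))
}

parse_genotype <- function(g, what) {
  phased <- grepl("|", g, fixed = TRUE)
  al <- strsplit(gsub("[|/]", "", g), "")
  bad <- lengths(al) != 2L | !vapply(al, function(a)
    all(a %in% c("C", "T")), logical(1))
  if (any(bad)) stopf("%s: genotypes must be two alleles over {C,T}", what)
  list(a1 = vapply(al, `[`, "", 1L), a2 = vapply(al, `[`, "", 2L),
       phased = phased)
}

#' Derive APOE epsilon-4 dosage from rs429358 / rs7412 genotypes
#'
#' Haplotype definitions: epsilon-4 = (rs429358-C, rs7412-C), epsilon-3 =
#' (T, C), epsilon-2 = (T, T). Dosage is the count of epsilon-4 haplotypes;
#' risk groups are 0 = low, 1 = intermediate, 2 = high. Genotypes are given
#' as strings, `"C|T"` (phased, allele order aligned across the two sites)
#' or `"C/T"` (unphased). Unphased double heterozygotes (C/T at both sites)
#' are indeterminate (epsilon-2/epsilon-4 vs epsilon-1/epsilon-3): they are
#' returned as `NA` and counted in attribute `n_indeterminate`, with a
#' warning. The rare epsilon-1 haplotype (C, T) counts as carrying the
#' rs429358-C allele but not as epsilon-4.
#'
#' @param rs429358,rs7412 Character vectors of genotype strings.
#' @return Data frame with `apoe_dosage` (0/1/2 or `NA`) and `apoe_group`
#'   (`low`/`intermediate`/`high`); attribute `n_indeterminate` counts the
#'   excluded ambiguous genotypes.
#' @export
apoe_from_genotypes <- function(rs429358, rs7412) {
  if (length(rs429358) != length(rs7412))
    stopf("genotype vectors must have equal length")
  g1 <- parse_genotype(rs429358, "rs429358")
  g2 <- parse_genotype(rs7412, "rs7412")
  hap_is_e4 <- function(a429, a7412) a429 == "C" & a7412 == "C"
  dosage <- as.integer(hap_is_e4(g1$a1, g2$a1) + hap_is_e4(g1$a2, g2$a2))
  het1 <- g1$a1 != g1$a2
  het2 <- g2$a1 != g2$a2
  ambiguous <- het1 & het2 & !(g1$phased & g2$phased)
  if (any(ambiguous)) {
    dosage[ambiguous] <- NA_integer_
    warnf("%d unphased double-heterozygote genotype(s) are indeterminate; set to NA",
          sum(ambiguous))
  }
  grp <- factor(c("low", "intermediate", "high")[dosage + 1L],
                levels = c("low", "intermediate", "high"))
  structure(data.frame(apoe_dosage = dosage, apoe_group = grp),
            n_indeterminate = sum(ambiguous))
}
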