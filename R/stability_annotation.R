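#' Statistical-stability screen for an interaction hit
#'
#' Refits the interaction model after removing observations whose
#' standardized Pearson residual exceeds `residual_threshold` in absolute
#' value.  A change of an order of magnitude or more in either the odds
#' ratio or the p-value marks the result as statistically unstable.  Results
#' whose interaction SE exceeds `se_max` fail the SE filter regardless of
#' the refit.
#'
#' @inheritParams robust_score_test
#' @param snp_id label carried into the verdict.
#' @param residual_threshold outlier cut on |standardized Pearson residual|,
#'   default 4; `Inf` disables outlier removal.
#' @param se_max SE filter threshold, default 10.
#' @return one-row `data.frame` (a stability verdict): `snp`,
#'   `outliers_removed`, `or_before`, `or_after`, `p_before`, `p_after`,
#'   `stable`, `se_filter_pass`, `reason`.
#' @export
stability_screen <- function(g, e, y, covariates = NULL, snp_id = "snp",
                             residual_threshold = 4, se_max = 10) {
  fit0 <- fit_interaction_model(g, e, y, covariates, snp_id = snp_id,
                                se_max = se_max)
  if (!isTRUE(fit0$converged)) {
    stop("original interaction fit did not converge for ", snp_id)
  }
  verdict <- data.frame(snp = snp_id, outliers_removed = 0L,
                        or_before = fit0$or_gxe, or_after = NA_real_,
                        p_before = fit0$p_raw, p_after = NA_real_,
                        stable = NA, se_filter_pass = fit0$se_filter_pass,
                        reason = "", stringsAsFactors = FALSE)
  X <- cbind(1, g = g, e = e, gxe = g * e)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  keep <- stats::complete.cases(X) & !is.na(y)
  Xc <- X[keep, , drop = FALSE]
  yc <- y[keep]
  lf <- .logistic_fit(Xc, yc)
  # standardized Pearson residuals: (y - p) / sqrt(p(1-p)(1 - h))
  p_hat <- lf$p_hat
  w <- p_hat * (1 - p_hat)
  Xw <- Xc * sqrt(w)
  h <- rowSums((Xw %*% solve(crossprod(Xw))) * Xw)
  r_std <- (yc - p_hat) / sqrt(pmax(w * (1 - h), 1e-12))
  out_idx <- which(abs(r_std) > residual_threshold)
  verdict$outliers_removed <- length(out_idx)
  if (length(out_idx) == 0) {
    verdict$or_after <- verdict$or_before
    verdict$p_after <- verdict$p_before
    verdict$stable <- TRUE
    return(verdict)
  }
  sub <- which(keep)[-out_idx]
  fit1 <- fit_interaction_model(g[sub], e[sub], y[sub],
                                if (is.null(covariates)) NULL else
                                  as.matrix(covariates)[sub, , drop = FALSE],
                                snp_id = snp_id, se_max = se_max)
  if (!isTRUE(fit1$converged)) {
    verdict$stable <- FALSE
    verdict$reason <- "refit without outliers did not converge"
    return(verdict)
  }
  verdict$or_after <- fit1$or_gxe
  verdict$p_after <- fit1$p_raw
  verdict$stable <- abs(log10(verdict$or_after / verdict$or_before)) < 1 &&
    abs(log10(verdict$p_after / verdict$p_before)) < 1
  verdict
}

#' Composite linkage-disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of the dosage vectors over pairwise-complete
#' subjects — the standard phase-free surrogate for haplotype r^2.
#'
#' @param panel a [genotype_panel()].
#' @param snp_a,snp_b variant ids or column indices.
#' @return r^2 in `[0, 1]`; `NA` with a warning if either variant is
#'   monomorphic in the pairwise-complete subset or fewer than 2 complete
#'   pairs exist.
#' @export
pairwise_r2 <- function(panel, snp_a, snp_b) {
  a <- panel$dosages[, snp_a]
  b <- panel$dosages[, snp_b]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) {
    warning("fewer than 2 pairwise-complete calls; r2 undefined")
    return(NA_real_)
  }
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    warning("variant monomorphic in the pairwise-complete subset; r2 undefined")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])^2
}

#' Variants within a flanked gene window
#'
#' @param variants data.frame with `chrom` and `pos` (1-based inclusive).
#' @param gene list or vector with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param flank bases added on each side, default 1e6 (1 Mb).
#' @return the subset of `variants` with `pos` in
#'   `[start - flank, end + flank]` on the gene's chromosome.
#' @export
gene_window <- function(variants, gene, flank = 1e6) {
  gene <- as.list(gene)
  lo <- as.numeric(gene$start) - flank
  hi <- as.numeric(gene$end) + flank
  sel <- variants$chrom == as.character(gene$chrom) &
    variants$pos >= lo & variants$pos <= hi
  variants[sel, , drop = FALSE]
}

#' CpG-site creation or disruption by a substitution
#'
#' A CpG dinucleotide is present at the variant position iff the 5' flank is
#' `C` and the base is `G`, or the base is `C` and the 3' flank is `G`.
#' Comparing presence for the reference and alternate base classifies the
#' substitution.  Evaluated on the given strand only.
#'
#' @param flank5,ref,alt,flank3 single bases in `A`/`C`/`G`/`T` (ambiguous
#'   IUPAC codes are rejected).
#' @return `"destroys_cpg"`, `"creates_cpg"`, or `"none"`.
#' @export
cpg_change <- function(flank5, ref, alt, flank3) {
  bases <- toupper(c(flank5, ref, alt, flank3))
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be unambiguous A/C/G/T")
  }
  has_cpg <- function(b) {
    (bases[1] == "C" && b == "G") || (b == "C" && bases[4] == "G")
  }
  before <- has_cpg(bases[2])
  after <- has_cpg(bases[3])
  if (before && !after) "destroys_cpg"
  else if (!before && after) "creates_cpg"
  else "none"
}
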