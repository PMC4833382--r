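.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_ambiguous_pair <- function(a1, a2) {
  !is.na(.complement[a1]) && identical(unname(.complement[a1]), a2)
}

#' Align two cohort summary records to a common effect allele
#'
#' If cohort B's effect allele is cohort A's other allele, B's beta is
#' sign-flipped and its allele frequency complemented.  Strand-ambiguous
#' variants (A/T or C/G) whose frequency is uninformative (both MAFs in
#' `[0.4, 0.6]`) are flagged unresolvable and should be excluded from
#' meta-analysis.
#'
#' @param record_a,record_b lists or one-row data.frames with fields `snp`,
#'   `effect_allele`, `other_allele`, `beta`, `maf` (and optionally `se`,
#'   `p`).
#' @return list with `a`, `b` (aligned), `effect_allele`, `flipped`, and
#'   `ambiguous`.
#' @export
align_alleles <- function(record_a, record_b) {
  a <- as.list(record_a); b <- as.list(record_b)
  if (!identical(a$snp, b$snp)) {
    stop("records are for different variants: ", a$snp, " vs ", b$snp)
  }
  same <- identical(a$effect_allele, b$effect_allele) &&
    identical(a$other_allele, b$other_allele)
  flipped <- identical(a$effect_allele, b$other_allele) &&
    identical(a$other_allele, b$effect_allele)
  if (!same && !flipped) {
    stop("incompatible allele sets for variant ", a$snp, ": ",
         a$effect_allele, "/", a$other_allele, " vs ",
         b$effect_allele, "/", b$other_allele)
  }
  if (flipped) {
    b$beta <- -b$beta
    b$maf <- 1 - b$maf
    tmp <- b$effect_allele
    b$effect_allele <- b$other_allele
    b$other_allele <- tmp
  }
  ambiguous <- .is_ambiguous_pair(a$effect_allele, a$other_allele) &&
    min(a$maf, 1 - a$maf) >= 0.4 && min(b$maf, 1 - b$maf) >= 0.4
  list(a = a, b = b, effect_allele = a$effect_allele,
       flipped = flipped, ambiguous = ambiguous)
}

#' Fixed-effect inverse-variance meta-analysis of aligned cohort records
#'
#' Weights are `w = 1/se^2`; the combined effect is `sum(w b) / sum(w)` with
#' standard error `(sum w)^(-1/2)` and a two-sided normal p-value.  The
#' relaxed MAF rule retains a variant when its MAF is >= `maf_min` in at
#' least one contributing cohort.
#'
#' @param records data.frame, one row per cohort for a single variant, with
#'   columns `beta`, `se`, and optionally `maf`, `p`, `cohort`, `snp`,
#'   `effect_allele`; betas must already be aligned to a common effect
#'   allele (see [align_alleles()]).
#' @param maf_min the relaxed MAF threshold (default 0.05); `NULL` skips the
#'   rule.
#' @return one-row `data.frame` (a meta record): `snp`, `effect_allele`,
#'   `n_cohorts`, `beta_meta`, `se_meta`, `z_meta`, `p_meta`, `consistent`
#'   (same aligned sign; `NA` unless >= 2 cohorts contribute),
#'   `maf_rule_pass`, `reason` (non-empty when nothing could be combined).
#' @export
inverse_variance_meta <- function(records, maf_min = 0.05) {
  records <- as.data.frame(records)
  stopifnot(all(c("beta", "se") %in% names(records)))
  snp <- if ("snp" %in% names(records)) records$snp[1] else NA_character_
  eff <- if ("effect_allele" %in% names(records)) records$effect_allele[1]
         else NA_character_
  empty <- function(reason, maf_pass = NA) {
    data.frame(snp = snp, effect_allele = eff, n_cohorts = 0L,
               beta_meta = NA_real_, se_meta = NA_real_, z_meta = NA_real_,
               p_meta = NA_real_, consistent = NA, maf_rule_pass = maf_pass,
               reason = reason, stringsAsFactors = FALSE)
  }
  usable <- is.finite(records$beta) & is.finite(records$se) & records$se > 0
  maf_pass <- TRUE
  if (!is.null(maf_min) && "maf" %in% names(records)) {
    maf_pass <- any(records$maf[usable] >= maf_min, na.rm = TRUE)
  }
  if (!maf_pass) return(empty("MAF below threshold in every cohort", FALSE))
  r <- records[usable, , drop = FALSE]
  if (nrow(r) == 0) return(empty("no cohort with a finite standard error", maf_pass))

  w <- 1 / r$se^2
  beta <- sum(w * r$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  data.frame(snp = snp, effect_allele = eff, n_cohorts = nrow(r),
             beta_meta = beta, se_meta = se, z_meta = z,
             p_meta = 2 * stats::pnorm(-abs(z)),
             consistent = if (nrow(r) >= 2) {
               length(unique(sign(r$beta[r$beta != 0]))) <= 1
             } else NA,
             maf_rule_pass = maf_pass, reason = "",
             stringsAsFactors = FALSE)
}

#' Classify scan and meta-analysis results into significance tiers
#'
#' Tags each variant: `genome_wide` (p < 5e-8 in some stratum), `suggestive`
#' (p < 1e-5 in some stratum), `replicated` (suggestive in one stratum and
#' p < 0.05 in another), `consistent` (same direction of effect after allele
#' alignment across strata), and `meta_suggestive` (meta-analysis
#' p < 1e-5).  Per-stratum classification uses the recalibrated p-value
#' where one exists, the raw score p otherwise.
#'
#' @param scan_results results from [run_scan()] (possibly recalibrated).
#' @param meta_records optional data.frame of meta records (rows from
#'   [inverse_variance_meta()]).
#' @param genome_wide,suggestive,replication thresholds; defaults 5e-8,
#'   1e-5, 0.05.
#' @return `data.frame`, one row per variant: `snp`, `chrom`, `pos`, per-tier
#'   logical flags, and `p_min` (smallest per-stratum p).
#' @export
classify_hits <- function(scan_results, meta_records = NULL,
                          genome_wide = 5e-8, suggestive = 1e-5,
                          replication = 0.05) {
  p_final <- ifelse(is.na(scan_results$p_adjusted), scan_results$p_raw,
                    scan_results$p_adjusted)
  sp <- split(seq_len(nrow(scan_results)), scan_results$snp)
  rows <- lapply(names(sp), function(id) {
    i <- sp[[id]]
    p <- p_final[i]
    betas <- scan_results$beta_gxe[i]
    effs <- scan_results$effect_allele[i]
    # align signs to the first stratum's effect allele before comparing
    aligned <- ifelse(effs == effs[1], betas, -betas)
    ok <- !is.na(p)
    sugg <- ok & p < suggestive
    repl <- any(sugg) && any(ok & !sugg & p < replication) ||
      sum(sugg) >= 2
    data.frame(snp = id,
               chrom = scan_results$chrom[i][1],
               pos = scan_results$pos[i][1],
               genome_wide = any(ok & p < genome_wide),
               suggestive = any(sugg),
               replicated = isTRUE(repl) && length(i) >= 2,
               consistent = if (sum(!is.na(aligned)) >= 2) {
                 length(unique(sign(aligned[!is.na(aligned) & aligned != 0]))) <= 1
               } else NA,
               p_min = if (any(ok)) min(p[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$meta_suggestive <- FALSE
  if (!is.null(meta_records) && nrow(meta_records) > 0) {
    ms <- meta_records$snp[!is.na(meta_records$p_meta) &
                             meta_records$p_meta < suggestive]
    out$meta_suggestive <- out$snp %in% ms
    mcons <- meta_records$consistent[match(out$snp, meta_records$snp)]
    use <- is.na(out$consistent) & !is.na(mcons)
    out$consistent[use] <- mcons[use]
  }
  out <- out[order(out$p_min), ]
  rownames(out) <- NULL
  out
}
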