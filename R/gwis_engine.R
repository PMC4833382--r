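#' Model specification for the interaction scan
#'
#' The primary model adjusts for age, sex and ancestry principal components;
#' the clinical variant adds BMI and binary indicators for hypertension,
#' smoking, diabetes and dyslipidemia.  Genetic coding is additive (minor
#' allele count) and the interaction is multiplicative on the logit scale.
#'
#' @param covariates character vector of sample-frame columns used as
#'   adjustment covariates.
#' @param clinical logical; append the five clinical covariates.
#' @param n_pcs principal components per stratum: a single count or a named
#'   vector (names = stratum labels); 0 disables PC adjustment.
#' @return a `model_spec` list.
#' @export
model_spec <- function(covariates = c("age", "sex"), clinical = FALSE,
                       n_pcs = 2) {
  if (isTRUE(clinical)) {
    covariates <- union(covariates, c("bmi", "hypertension", "smoking",
                                      "diabetes", "dyslipidemia"))
  }
  stopifnot(all(n_pcs >= 0))
  structure(list(covariates = covariates, clinical = isTRUE(clinical),
                 n_pcs = n_pcs),
            class = "model_spec")
}

# Internal logistic IRLS via glm.fit with the package's convergence policy.
# Separation is detected through diverging coefficients on the
# per-column-SD scale (a separated fit sends at least one scaled
# coefficient towards infinity), not through boundary fitted values, which
# legitimate strong effects with long-tailed covariates also produce.
.logistic_fit <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  p_hat <- fit$fitted.values
  aliased <- any(is.na(fit$coefficients))
  sep <- FALSE
  if (!aliased) {
    col_sd <- apply(X, 2, stats::sd)
    col_sd[col_sd == 0] <- 1  # intercept and constant columns on unit scale
    sep <- max(abs(fit$coefficients) * col_sd) > 15
  }
  list(fit = fit, p_hat = p_hat,
       converged = isTRUE(fit$converged) && !sep && !aliased,
       separated = sep)
}

#' Robust score test for a gene-environment interaction term
#'
#' Tests the multiplicative interaction `g * e` against a null logistic model
#' containing the intercept, genetic and exposure main effects and any
#' adjustment covariates.  With `z = g * e` and null fitted probabilities
#' `p`, the score is `U = sum(z_i (y_i - p_i))`; `z` is projected out of the
#' null design under the IRLS weights `W = diag(p(1-p))`, giving
#' `a = z - X (X'WX)^{-1} X'W z`, and the empirical (sandwich-type) variance
#' is `V_robust = sum(a_i^2 (y_i - p_i)^2)`.  The statistic `T = U^2 /
#' V_robust` is referred to the upper tail of chi-squared with 1 df.  The
#' model-based variance `a'Wz` is returned for diagnostics.
#'
#' @param g additive genotype dosage vector (0/1/2, NA allowed).
#' @param e scaled exposure vector.
#' @param y binary outcome vector.
#' @param covariates optional numeric matrix or data.frame of adjustment
#'   covariates (no intercept column).
#' @return list with `U`, `V_robust`, `V_model`, `statistic`, `p.value`,
#'   `n`, and `converged`.  On null-model non-convergence, separation, or a
#'   non-positive variance, `converged` is `FALSE` and no p-value is emitted.
#' @export
robust_score_test <- function(g, e, y, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, g = g, e = e)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  z <- X[, "g"] * X[, "e"]

  out <- list(U = NA_real_, V_robust = NA_real_, V_model = NA_real_,
              statistic = NA_real_, p.value = NA_real_, n = sum(keep),
              converged = FALSE)
  lf <- tryCatch(.logistic_fit(X, y), error = function(err) NULL)
  if (is.null(lf) || !lf$converged) return(out)

  p_hat <- lf$p_hat
  w <- p_hat * (1 - p_hat)
  XtWX <- crossprod(X, w * X)
  proj <- tryCatch(solve(XtWX, crossprod(X, w * z)), error = function(err) NULL)
  if (is.null(proj)) return(out)
  a <- drop(z - X %*% proj)

  U <- sum(z * (y - p_hat))
  V_rob <- sum(a^2 * (y - p_hat)^2)
  V_mod <- sum(a * w * z)
  out$U <- U; out$V_robust <- V_rob; out$V_model <- V_mod
  if (!is.finite(V_rob) || V_rob <= max(1e-12, 1e-10 * sum(z^2))) return(out)
  out$statistic <- U^2 / V_rob
  out$p.value <- stats::pchisq(out$statistic, df = 1, lower.tail = FALSE)
  out$converged <- TRUE
  out
}

#' Fit the per-variant logistic interaction model
#'
#' Maximum-likelihood logistic regression of the outcome on genotype,
#' exposure, their product, and the adjustment covariates.  Wald estimates
#' (beta, SE, OR) are reported for the interaction and both main effects; the
#' interaction p-value comes from [robust_score_test()] on the corresponding
#' null model.  The odds ratio is per minor allele per exposure IQR.
#'
#' @inheritParams robust_score_test
#' @param snp_id,stratum labels carried into the result row.
#' @param se_max Wald SEs above this mark the result as failing the SE
#'   filter (default 10).
#' @return one-row `data.frame` (an interaction result): `snp`, `stratum`,
#'   `n`, `maf`, `beta_gxe`, `se_gxe`, `or_gxe`, `score_U`, `score_V_robust`,
#'   `stat_T`, `p_raw`, `p_adjusted` (NA until recalibration), `beta_g`,
#'   `se_g`, `p_g`, `beta_e`, `se_e`, `p_e`, `converged`, `se_filter_pass`,
#'   `stable` (NA until screened).
#' @export
fit_interaction_model <- function(g, e, y, covariates = NULL, snp_id = "snp",
                                  stratum = NA_character_, se_max = 10) {
  X <- cbind(`(Intercept)` = 1, g = g, e = e, gxe = g * e)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  keep <- stats::complete.cases(X) & !is.na(y)
  Xc <- X[keep, , drop = FALSE]
  yc <- y[keep]

  res <- data.frame(snp = snp_id, stratum = stratum, n = sum(keep),
                    maf = {
                      gg <- Xc[, "g"]
                      p <- mean(gg) / 2
                      min(p, 1 - p)
                    },
                    beta_gxe = NA_real_, se_gxe = NA_real_, or_gxe = NA_real_,
                    score_U = NA_real_, score_V_robust = NA_real_,
                    stat_T = NA_real_, p_raw = NA_real_, p_adjusted = NA_real_,
                    beta_g = NA_real_, se_g = NA_real_, p_g = NA_real_,
                    beta_e = NA_real_, se_e = NA_real_, p_e = NA_real_,
                    converged = FALSE, se_filter_pass = NA,
                    stable = NA, stringsAsFactors = FALSE)

  lf <- tryCatch(.logistic_fit(Xc, yc), error = function(err) NULL)
  st <- robust_score_test(g, e, y, covariates)
  res$score_U <- st$U
  res$score_V_robust <- st$V_robust
  res$stat_T <- st$statistic
  res$p_raw <- st$p.value

  if (is.null(lf) || !lf$converged || !st$converged) return(res)
  cf <- lf$fit$coefficients
  w <- lf$p_hat * (1 - lf$p_hat)
  vc <- tryCatch(solve(crossprod(Xc, w * Xc)), error = function(err) NULL)
  if (is.null(vc)) return(res)
  se <- sqrt(diag(vc))
  wald_p <- function(term) {
    2 * stats::pnorm(-abs(cf[term] / se[term]))
  }
  res$beta_gxe <- unname(cf["gxe"]); res$se_gxe <- unname(se["gxe"])
  res$or_gxe <- exp(res$beta_gxe)
  res$beta_g <- unname(cf["g"]); res$se_g <- unname(se["g"])
  res$p_g <- unname(wald_p("g"))
  res$beta_e <- unname(cf["e"]); res$se_e <- unname(se["e"])
  res$p_e <- unname(wald_p("e"))
  res$converged <- TRUE
  res$se_filter_pass <- res$se_gxe <= se_max
  res
}

#' Race/ancestry-stratified genome-wide interaction scan
#'
#' Stage 1 of the analysis: within each stratum the exposure is re-scaled by
#' that stratum's IQR, principal components are computed from the stratum's
#' genotypes, variants failing the stratum MAF filter are skipped, genotype
#' is recoded to that stratum's minor allele, and the interaction model is
#' fitted per variant.  Results carry significance tags at the genome-wide
#' (p < 5e-8) and suggestive (p < 1e-5) tiers.
#'
#' @param panel a QC'd [genotype_panel()].
#' @param frame sample frame aligned with `panel` (matched by `sample_id`
#'   against the panel's subject ids).
#' @param spec a [model_spec()].
#' @param maf_min per-stratum MAF filter (default 0.05; set lower to retain
#'   variants for relaxed-MAF meta-analysis).
#' @param genome_wide,suggestive significance thresholds for tags.
#' @param se_max SE filter threshold passed through to the model fit.
#' @return `data.frame`, one row per (stratum, variant) passing that
#'   stratum's MAF filter, in stratum-then-position order, with columns
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, the interaction-result
#'   fields of [fit_interaction_model()], and `tag`.
#' @export
run_scan <- function(panel, frame, spec = model_spec(), maf_min = 0.05,
                     genome_wide = 5e-8, suggestive = 1e-5, se_max = 10) {
  stopifnot(inherits(panel, "genotype_panel"), is.data.frame(frame))
  ord <- match(panel$subjects, frame$sample_id)
  if (anyNA(ord)) stop("sample frame is missing ids present in the panel")
  frame <- frame[ord, , drop = FALSE]
  strata <- unique(frame$stratum)
  miss_cov <- setdiff(spec$covariates, names(frame))
  if (length(miss_cov) > 0) {
    stop("sample frame lacks covariate(s): ", paste(miss_cov, collapse = ", "))
  }
  n_pcs <- spec$n_pcs
  if (is.null(names(n_pcs))) n_pcs <- stats::setNames(rep_len(n_pcs, length(strata)), strata)

  out <- vector("list", length(strata))
  for (si in seq_along(strata)) {
    s <- strata[si]
    rows <- which(frame$stratum == s)
    if (length(rows) < 50) {
      warning("stratum ", s, " has only ", length(rows), " subjects")
    }
    sub_frame <- frame[rows, , drop = FALSE]
    sub_panel <- panel[rows, ]
    e <- iqr_scale(sub_frame$distance_m)$scaled
    covs <- as.matrix(sub_frame[, spec$covariates, drop = FALSE])
    k <- n_pcs[[s]]
    if (!is.null(k) && k > 0) {
      pcs <- suppressWarnings(compute_pcs(sub_panel, k))
      covs <- cbind(covs, pcs)
    }
    y <- sub_frame$outcome
    mafs <- suppressWarnings(maf(sub_panel))
    keep <- which(!is.na(mafs) & mafs >= maf_min)
    res_s <- vector("list", length(keep))
    for (ji in seq_along(keep)) {
      j <- keep[ji]
      g <- sub_panel$dosages[, j]
      vr <- sub_panel$variants[j, ]
      p_alt <- mean(g, na.rm = TRUE) / 2
      if (p_alt > 0.5) {  # recode to this stratum's minor allele
        g <- 2L - g
        eff <- vr$ref; oth <- vr$alt
      } else {
        eff <- vr$alt; oth <- vr$ref
      }
      r <- fit_interaction_model(g, e, y, covariates = covs, snp_id = vr$id,
                                 stratum = s, se_max = se_max)
      r <- cbind(data.frame(chrom = vr$chrom, pos = vr$pos,
                            effect_allele = eff, other_allele = oth,
                            stringsAsFactors = FALSE), r)
      res_s[[ji]] <- r
    }
    out[[si]] <- if (length(res_s) > 0) do.call(rbind, res_s) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) {
    stop("no variant passed the per-stratum MAF filter")
  }
  res$tag <- ifelse(!is.na(res$p_raw) & res$p_raw < genome_wide, "genome_wide",
                    ifelse(!is.na(res$p_raw) & res$p_raw < suggestive,
                           "suggestive", ""))
  rownames(res) <- NULL
  res
}

#' Write scan results as TSV
#' @param results scan results from [run_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
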