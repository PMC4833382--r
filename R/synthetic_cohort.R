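#' Configuration for the synthetic two-ancestry cohort generator
#'
#' The defaults emulate the study conditions of a two-ancestry catheterization
#' cohort: strata of 1623 and 554 subjects, divergent allele frequencies
#' (Balding-Nichols `fst`), block LD via a latent AR(1) Gaussian copula, a
#' right-skewed residential distance-to-roadway exposure with an IQR near
#' 641 m, and a binary outcome with ~6.3% prevalence on the logit scale.
#'
#' @param n_per_stratum integer vector of subjects per ancestry stratum.
#' @param n_snps number of variants.
#' @param block_size variants per LD block (`<= n_snps`).
#' @param rho latent within-block AR(1) correlation, in `[0, 1)`.
#' @param fst Balding-Nichols divergence between strata, in `[0, 0.5]`;
#'   with more than one stratum and `rho > 0`, `fst = 0` is rejected because
#'   LD cannot produce between-stratum frequency divergence.
#' @param maf_range interval for the ancestral allele frequency.
#' @param exposure_log_mean,exposure_log_sd log-normal parameters for the
#'   distance exposure in meters (defaults give an IQR near 641 m).
#' @param causal_snps list of `list(snp =, beta_g =, beta_gxe =)` entries:
#'   variant column index, genetic main effect and interaction effect on the
#'   log-odds scale (per minor allele, per exposure IQR).
#' @param beta_e exposure main effect per IQR of distance; default `log(0.88)`
#'   (greater distance from traffic is protective).
#' @param target_prevalence outcome prevalence the intercept is calibrated to.
#' @param covariate_effects named vector with elements `age` (per year,
#'   centred) and `sex` (female indicator) on the log-odds scale.
#' @param age_mean,age_sd,sex_prob per-stratum age and sex distributions,
#'   recycled across strata.
#' @param clinical logical; also draw the five binary/continuous clinical
#'   covariates (BMI, hypertension, smoking, diabetes, dyslipidemia) used by
#'   the clinical model variant.  They do not affect the outcome.
#' @param missing_rate completely-at-random missing-call rate.
#' @param seed single integer; all substreams derive from it, and an identical
#'   config reproduces bit-identical output.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_per_stratum = c(1623L, 554L),
                       n_snps = 1000L,
                       block_size = 10L,
                       rho = 0.3,
                       fst = 0.1,
                       maf_range = c(0.05, 0.5),
                       exposure_log_mean = 6.09,
                       exposure_log_sd = 1.0,
                       causal_snps = list(),
                       beta_e = log(0.88),
                       target_prevalence = 0.0634,
                       covariate_effects = c(age = 0.03, sex = -0.3),
                       age_mean = c(61.2, 56.3),
                       age_sd = c(11.9, 11.4),
                       sex_prob = c(0.394, 0.536),
                       clinical = FALSE,
                       missing_rate = 0.002,
                       seed = 1L) {
  n_per_stratum <- as.integer(n_per_stratum)
  n_snps <- as.integer(n_snps)
  block_size <- as.integer(block_size)
  stopifnot(length(n_per_stratum) >= 1, all(n_per_stratum > 0),
            n_snps >= 1, block_size >= 1,
            rho >= 0, rho < 1,
            fst >= 0, fst <= 0.5,
            length(maf_range) == 2,
            maf_range[1] >= 0.01, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            exposure_log_sd > 0,
            target_prevalence > 0, target_prevalence < 1,
            missing_rate >= 0, missing_rate < 1,
            length(seed) == 1, is.finite(seed))
  if (block_size > n_snps) {
    stop("block_size (", block_size, ") exceeds n_snps (", n_snps, ")")
  }
  if (fst == 0 && rho > 0 && length(n_per_stratum) > 1) {
    stop("fst = 0 with rho > 0 cannot produce between-stratum divergence; ",
         "set fst > 0 for a multi-stratum panel or use a single stratum")
  }
  if (!all(c("age", "sex") %in% names(covariate_effects))) {
    stop("covariate_effects must name 'age' and 'sex'")
  }
  for (cs in causal_snps) {
    if (!all(c("snp", "beta_g", "beta_gxe") %in% names(cs))) {
      stop("each causal_snps entry needs fields snp, beta_g, beta_gxe")
    }
    if (cs$snp < 1 || cs$snp > n_snps) stop("causal snp index out of range")
  }
  k <- length(n_per_stratum)
  cfg <- list(n_per_stratum = n_per_stratum, n_snps = n_snps,
              block_size = block_size, rho = rho, fst = fst,
              maf_range = maf_range,
              exposure_log_mean = exposure_log_mean,
              exposure_log_sd = exposure_log_sd,
              causal_snps = causal_snps, beta_e = beta_e,
              target_prevalence = target_prevalence,
              covariate_effects = covariate_effects,
              age_mean = rep_len(age_mean, k),
              age_sd = rep_len(age_sd, k),
              sex_prob = rep_len(sex_prob, k),
              clinical = isTRUE(clinical),
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# deterministic substream seeds derived from the single config seed
.substream <- function(seed, stream) {
  (as.integer(seed) + c(genotype = 0L, phenotype = 1000003L)[[stream]]) %% .Machine$integer.max
}

#' Simulate a stratified genotype panel
#'
#' Per variant an ancestral frequency is drawn uniformly on `maf_range`; each
#' stratum's frequency then comes from the Balding-Nichols
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` distribution (or equals the ancestral
#' frequency when `fst = 0`).  Within each LD block a latent AR(1) Gaussian
#' with correlation `rho` is thresholded at the Hardy-Weinberg genotype-class
#' quantiles, so marginal genotype frequencies are HWE while adjacent-variant
#' dosage correlation decays geometrically; blocks are independent.  Missing
#' calls are injected completely at random.
#'
#' @param config a [sim_config()].
#' @return a [genotype_panel()] with an attribute `stratum` (per-subject
#'   stratum labels, `"S1"`, `"S2"`, ...).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, "genotype"))
  m <- config$n_snps
  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  k <- length(config$n_per_stratum)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / config$block_size))

  strata_mats <- vector("list", k)
  for (s in seq_len(k)) {
    n <- config$n_per_stratum[s]
    if (config$fst > 0) {
      a <- p_anc * (1 - config$fst) / config$fst
      b <- (1 - p_anc) * (1 - config$fst) / config$fst
      p_s <- stats::rbeta(m, a, b)
      p_s <- pmin(pmax(p_s, 1e-4), 1 - 1e-4)
    } else {
      p_s <- p_anc
    }
    z <- matrix(0, n, m)
    rho <- config$rho
    for (bl in blocks) {
      z[, bl[1]] <- stats::rnorm(n)
      if (length(bl) > 1) {
        for (j in bl[-1]) {
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
        }
      }
    }
    # HWE thresholds: P(0) = (1-p)^2, P(2) = p^2
    q0 <- stats::qnorm((1 - p_s)^2)
    q2 <- stats::qnorm(1 - p_s^2)
    dos <- sweep(z, 2, q0, ">") + sweep(z, 2, q2, ">")
    storage.mode(dos) <- "integer"
    strata_mats[[s]] <- dos
  }
  dosages <- do.call(rbind, strata_mats)
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dosages)) < config$missing_rate
    dosages[miss] <- NA_integer_
  }
  stratum <- rep(paste0("S", seq_len(k)), config$n_per_stratum)
  subjects <- sprintf("subj%05d", seq_len(nrow(dosages)))
  variants <- data.frame(chrom = "1",
                         pos = 1000L * seq_len(m),
                         id = sprintf("snp%05d", seq_len(m)),
                         ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  panel <- genotype_panel(dosages, variants, subjects)
  attr(panel, "stratum") <- stratum
  attr(panel, "stratum_freq") <- NULL
  panel
}

#' Simulate exposure, covariates and a prevalence-calibrated binary outcome
#'
#' Distance exposure is log-normal and scaled by its IQR; the outcome is
#' Bernoulli with logit `b0 + beta_g g + beta_e e + beta_gxe g e +
#' beta_age (age - mean age) + beta_sex sex`, where the intercept `b0` is
#' found by root-finding so the expected prevalence over the simulated
#' covariate distribution matches `target_prevalence` to within 0.002.
#' Missing causal genotypes enter the linear predictor at their mean dosage.
#'
#' @param panel a panel from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return a `data.frame` (the sample frame) with columns `sample_id`,
#'   `stratum`, `outcome`, `distance_m`, `exposure_scaled`, `age`, `sex`, and
#'   the clinical flags when `config$clinical`; attribute `iqr_m` records the
#'   IQR used for scaling.
#' @export
simulate_phenotypes <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- n_subjects(panel)
  if (n != sum(config$n_per_stratum)) {
    stop("panel has ", n, " subjects but config specifies ",
         sum(config$n_per_stratum))
  }
  stratum <- attr(panel, "stratum")
  if (is.null(stratum)) stratum <- rep("S1", n)
  set.seed(.substream(config$seed, "phenotype"))

  distance_m <- stats::rlnorm(n, config$exposure_log_mean, config$exposure_log_sd)
  sc <- iqr_scale(distance_m)
  e <- sc$scaled

  k <- length(config$n_per_stratum)
  idx <- split(seq_len(n), rep(seq_len(k), config$n_per_stratum))
  age <- numeric(n)
  sex <- integer(n)
  for (s in seq_len(k)) {
    age[idx[[s]]] <- stats::rnorm(length(idx[[s]]), config$age_mean[s],
                                  config$age_sd[s])
    sex[idx[[s]]] <- stats::rbinom(length(idx[[s]]), 1, config$sex_prob[s])
  }

  eta <- config$beta_e * e +
    config$covariate_effects[["age"]] * (age - mean(age)) +
    config$covariate_effects[["sex"]] * sex
  for (cs in config$causal_snps) {
    g <- panel$dosages[, cs$snp]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    eta <- eta + cs$beta_g * g + cs$beta_gxe * g * e
  }

  f <- function(b0) mean(stats::plogis(b0 + eta)) - config$target_prevalence
  root <- tryCatch(stats::uniroot(f, c(-40, 40), tol = 1e-12, maxiter = 1000),
                   error = function(err) {
                     stop("prevalence calibration failed: ",
                          conditionMessage(err))
                   })
  b0 <- root$root
  achieved <- mean(stats::plogis(b0 + eta))
  if (abs(achieved - config$target_prevalence) > 0.002) {
    stop(sprintf(
      "prevalence calibration did not converge: expected prevalence %.4f vs target %.4f",
      achieved, config$target_prevalence))
  }
  y <- stats::rbinom(n, 1, stats::plogis(b0 + eta))

  frame <- data.frame(sample_id = panel$subjects,
                      stratum = stratum,
                      outcome = y,
                      distance_m = distance_m,
                      exposure_scaled = e,
                      age = age,
                      sex = sex,
                      stringsAsFactors = FALSE)
  if (config$clinical) {
    bmi_mean <- rep_len(c(29.8, 32.1), k)
    bmi_sd <- rep_len(c(7.02, 7.99), k)
    hyp <- rep_len(c(0.644, 0.805), k)
    smo <- rep_len(c(0.502, 0.426), k)
    dia <- rep_len(c(0.264, 0.428), k)
    dys <- rep_len(c(0.608, 0.540), k)
    frame$bmi <- frame$hypertension <- frame$smoking <- frame$diabetes <-
      frame$dyslipidemia <- NA_real_
    for (s in seq_len(k)) {
      i <- idx[[s]]
      frame$bmi[i] <- stats::rnorm(length(i), bmi_mean[s], bmi_sd[s])
      frame$hypertension[i] <- stats::rbinom(length(i), 1, hyp[s])
      frame$smoking[i] <- stats::rbinom(length(i), 1, smo[s])
      frame$diabetes[i] <- stats::rbinom(length(i), 1, dia[s])
      frame$dyslipidemia[i] <- stats::rbinom(length(i), 1, dys[s])
    }
  }
  attr(frame, "iqr_m") <- sc$iqr
  attr(frame, "intercept") <- b0
  frame
}
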