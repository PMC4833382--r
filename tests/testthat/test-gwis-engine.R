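test_that("score test is exactly null on a case-control mirrored dataset", {
  set.seed(2)
  n <- 40
  g <- rbinom(n, 2, 0.3)
  e <- abs(rnorm(n)) + 0.1
  # every covariate pattern appears once with y = 1 and once with y = 0
  res <- robust_score_test(c(g, g), c(e, e), c(rep(1, n), rep(0, n)))
  expect_true(res$converged)
  expect_equal(res$U, 0, tolerance = 1e-10)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p.value, 1)
})

test_that("score and robust variance match the numerical-differentiation oracle", {
  for (seed in c(11, 12, 13)) {
    d <- make_gxe_data(60, beta_gxe = 0.4, prevalence = 0.3, seed = seed)
    impl <- robust_score_test(d$g, d$e, d$y, d$covariates)
    orac <- oracle_score(d$g, d$e, d$y, d$covariates)
    expect_true(impl$converged)
    expect_equal(impl$U, orac$U, tolerance = 1e-8)
    expect_equal(impl$V_robust, orac$V_robust, tolerance = 1e-8)
    expect_equal(impl$statistic, orac$statistic, tolerance = 1e-8)
  }
})

test_that("statistic is invariant to affine rescaling of covariates", {
  d <- make_gxe_data(300, beta_gxe = 0.3, prevalence = 0.2, seed = 14)
  base <- robust_score_test(d$g, d$e, d$y, d$covariates)
  rescaled <- d$covariates
  rescaled[, "age"] <- (rescaled[, "age"] - 50) / 7.3
  rescaled[, "sex"] <- 100 * rescaled[, "sex"] - 12
  alt <- robust_score_test(d$g, d$e, d$y, rescaled)
  expect_equal(alt$statistic, base$statistic, tolerance = 1e-8)
})

test_that("swapping allele labels flips effect signs and preserves the statistic", {
  d <- make_gxe_data(500, beta_gxe = 0.5, beta_g = 0.2, prevalence = 0.2,
                     seed = 15)
  f1 <- fit_interaction_model(d$g, d$e, d$y, d$covariates)
  f2 <- fit_interaction_model(2 - d$g, d$e, d$y, d$covariates)
  expect_equal(f2$beta_g, -f1$beta_g, tolerance = 1e-6)
  expect_equal(f2$beta_gxe, -f1$beta_gxe, tolerance = 1e-6)
  expect_equal(f2$stat_T, f1$stat_T, tolerance = 1e-6)
  expect_equal(f2$maf, f1$maf)
})

test_that("score and Wald p-values agree within a factor of two off the far tail", {
  # the asymptotic equivalence holds between the Wald test and the
  # model-based score statistic U^2 / V_model; the robust-variance variant
  # additionally absorbs misspecification and is checked only for sanity
  for (seed in 16:19) {
    d <- make_gxe_data(1500, beta_gxe = 0.35, prevalence = 0.2, seed = seed)
    fit <- fit_interaction_model(d$g, d$e, d$y, d$covariates)
    st <- robust_score_test(d$g, d$e, d$y, d$covariates)
    p_model <- pchisq(st$U^2 / st$V_model, 1, lower.tail = FALSE)
    z <- abs(fit$beta_gxe / fit$se_gxe)
    wald_p <- 2 * pnorm(-z)
    if (z < 4) {
      ratio <- p_model / wald_p
      expect_gt(ratio, 0.5)
      expect_lt(ratio, 2)
    }
    expect_gt(st$p.value, 0)
    expect_lt(st$p.value, 1)
  }
})

test_that("null interaction estimates are centred at zero", {
  est <- vapply(1:40, function(r) {
    d <- make_gxe_data(2000, beta_gxe = 0, prevalence = 0.1, seed = 300 + r)
    fit_interaction_model(d$g, d$e, d$y, d$covariates)$beta_gxe
  }, numeric(1))
  expect_lt(abs(median(est, na.rm = TRUE)), 0.05)
})

test_that("a planted moderate interaction is recovered within its 95% CI", {
  d <- make_gxe_data(20000, beta_gxe = log(2), seed = 5)
  fit <- fit_interaction_model(d$g, d$e, d$y, d$covariates)
  expect_true(fit$converged)
  expect_gt(log(2), fit$beta_gxe - 1.96 * fit$se_gxe)
  expect_lt(log(2), fit$beta_gxe + 1.96 * fit$se_gxe)
})

test_that("separated fits are flagged rather than reported", {
  set.seed(20)
  n <- 80
  g <- rbinom(n, 2, 0.3)
  e <- abs(rnorm(n))
  sep_cov <- c(rep(0, 40), rep(1, 40))
  y <- sep_cov  # covariate perfectly predicts the outcome
  fit <- fit_interaction_model(g, e, y, cbind(sep = sep_cov))
  expect_false(fit$converged)
  expect_true(is.na(fit$p_raw) || fit$p_raw == 1)
  st <- robust_score_test(g, e, y, cbind(sep = sep_cov))
  expect_false(st$converged)
  expect_true(is.na(st$p.value))
})

test_that("a null scan produces no suggestive hits and respects the MAF filter", {
  cfg <- sim_config(n_per_stratum = 400, n_snps = 200, fst = 0, rho = 0,
                    maf_range = c(0.05, 0.5), seed = 23)
  panel <- simulate_genotypes(cfg)
  frame <- simulate_phenotypes(panel, cfg)
  res <- run_scan(panel, frame, model_spec(n_pcs = 0), maf_min = 0.05)
  expect_true(all(res$tag == ""))
  mafs <- suppressWarnings(maf(panel))
  expect_setequal(res$snp, names(mafs)[!is.na(mafs) & mafs >= 0.05])
})

test_that("single-stratum scan equals a direct per-variant loop", {
  cfg <- sim_config(n_per_stratum = 300, n_snps = 10, fst = 0, rho = 0,
                    missing_rate = 0, seed = 24)
  panel <- simulate_genotypes(cfg)
  frame <- simulate_phenotypes(panel, cfg)
  res <- run_scan(panel, frame, model_spec(n_pcs = 0), maf_min = 0.05)
  e <- iqr_scale(frame$distance_m)$scaled
  covs <- cbind(age = frame$age, sex = frame$sex)
  for (r in seq_len(nrow(res))) {
    g <- panel$dosages[, res$snp[r]]
    if (mean(g, na.rm = TRUE) / 2 > 0.5) g <- 2L - g
    direct <- fit_interaction_model(g, e, frame$outcome, covs)
    expect_equal(res$beta_gxe[r], direct$beta_gxe)
    expect_equal(res$p_raw[r], direct$p_raw)
  }
})

test_that("per-stratum MAF filtering is independent across strata", {
  # variant common in stratum 1 but rare in stratum 2 appears once
  set.seed(26)
  d <- cbind(c(rbinom(200, 2, 0.3), rbinom(200, 2, 0.01)),
             rbinom(400, 2, 0.4))
  panel <- genotype_panel(d, data.frame(chrom = "1", pos = c(1L, 2L),
                                        id = c("rare2", "common"),
                                        ref = "A", alt = "G"),
                          subjects = sprintf("i%03d", 1:400))
  frame <- data.frame(sample_id = panel$subjects,
                      stratum = rep(c("S1", "S2"), each = 200),
                      outcome = rbinom(400, 1, 0.2),
                      distance_m = rlnorm(400, 6, 1),
                      age = rnorm(400, 60, 10), sex = rbinom(400, 1, 0.4))
  res <- run_scan(panel, frame, model_spec(n_pcs = 0), maf_min = 0.05)
  expect_equal(sum(res$snp == "rare2"), 1)
  expect_equal(res$stratum[res$snp == "rare2"], "S1")
  expect_equal(sum(res$snp == "common"), 2)
})
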