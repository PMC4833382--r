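# Independent oracles and small data builders shared across tests.

# Score-test oracle, deliberately on a different computational route than the
# package: the null model is fitted with formula-based stats::glm, the score
# U is obtained by central numeric differentiation of the binomial
# log-likelihood in the interaction coefficient at the null MLE, and the
# projection residual comes from an explicit weighted least-squares fit.
oracle_score <- function(g, e, y, covariates = NULL, h = 1e-5) {
  dat <- data.frame(y = y, g = g, e = e)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  dat <- dat[stats::complete.cases(dat), ]
  null_fit <- stats::glm(y ~ ., data = dat, family = binomial())
  eta0 <- stats::predict(null_fit, type = "link")
  z <- dat$g * dat$e
  loglik <- function(theta) {
    p <- stats::plogis(eta0 + theta * z)
    sum(dat$y * log(p) + (1 - dat$y) * log(1 - p))
  }
  U <- (loglik(h) - loglik(-h)) / (2 * h)
  p_hat <- stats::fitted(null_fit)
  w <- p_hat * (1 - p_hat)
  X <- stats::model.matrix(null_fit)
  wls <- stats::lm.wfit(X, z, w)
  a <- wls$residuals
  V_robust <- sum(a^2 * (dat$y - p_hat)^2)
  list(U = U, V_robust = V_robust, statistic = U^2 / V_robust)
}

# brute-force composite-LD r2: explicit sums, no cor()
oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  cab <- sum((a - mean(a)) * (b - mean(b))) / n
  va <- sum((a - mean(a))^2) / n
  vb <- sum((b - mean(b))^2) / n
  cab^2 / (va * vb)
}

# small handcrafted panel: 4 subjects x 3 variants
make_tiny_panel <- function() {
  d <- matrix(c(0L, 1L, 2L, NA,
                0L, 0L, 0L, 0L,
                2L, 2L, 2L, 1L), nrow = 4)
  genotype_panel(d,
                 data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                            id = c("v1", "v2", "v3"), ref = "A", alt = "G"),
                 subjects = paste0("s", 1:4))
}

# logistic GxE dataset with known truth, for fit/recovery tests
make_gxe_data <- function(n, beta_gxe = 0, beta_g = 0, beta_e = log(0.88),
                          maf = 0.3, prevalence = 0.0634, seed = 1) {
  set.seed(seed)
  g <- stats::rbinom(n, 2, maf)
  dist_m <- stats::rlnorm(n, 6.09, 1)
  e <- iqr_scale(dist_m)$scaled
  age <- stats::rnorm(n, 60, 12)
  sex <- stats::rbinom(n, 1, 0.43)
  eta <- beta_g * g + beta_e * e + beta_gxe * g * e +
    0.03 * (age - mean(age)) - 0.3 * sex
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - prevalence,
                       c(-30, 30))$root
  y <- stats::rbinom(n, 1, stats::plogis(b0 + eta))
  list(g = g, e = e, y = y, covariates = cbind(age = age, sex = sex),
       b0 = b0)
}

exact_binom_bounds <- function(n, p, conf = 0.99) {
  alpha <- (1 - conf) / 2
  c(stats::qbinom(alpha, n, p), stats::qbinom(1 - alpha, n, p)) / n
}
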