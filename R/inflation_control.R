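# chi-squared(1) median, the genomic-control denominator
.CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)

#' Median-based genomic-control lambda
#'
#' `lambda_m` is the median of (optionally subsampled) observed score
#' statistics divided by the chi-squared(1) median (0.4549364).  Values above
#' 1 indicate genome-wide inflation of the test statistics.
#'
#' @param stats vector of chi-squared(1)-scale statistics; non-finite values
#'   are excluded and counted.
#' @param subsample_size optional number of statistics to draw without
#'   replacement; `NULL` or any value >= the number available uses all.
#' @param seed seed for the subsample draw, recorded in the estimate; the
#'   global RNG state is left untouched.
#' @return object of class `lambda_estimate`: `lambda_m`, `n_stats_used`,
#'   `subsample_seed`, `basis = "median"`, `n_nonfinite_excluded`.
#' @export
estimate_lambda_median <- function(stats, subsample_size = NULL, seed = 1L) {
  finite <- is.finite(stats)
  n_excl <- sum(!finite)
  x <- stats[finite]
  if (length(x) < 100) {
    stop("need at least 100 finite statistics to estimate lambda (have ",
         length(x), ")")
  }
  if (!is.null(subsample_size) && subsample_size < length(x)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    x <- x[sample.int(length(x), subsample_size)]
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  structure(list(lambda_m = stats::median(x) / .CHISQ1_MEDIAN,
                 n_stats_used = length(x),
                 subsample_seed = seed,
                 basis = "median",
                 n_nonfinite_excluded = n_excl),
            class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
  cat(sprintf("genomic-control lambda (median basis): %.4f over %d statistics\n",
              x$lambda_m, x$n_stats_used))
  if (x$n_nonfinite_excluded > 0) {
    cat("  non-finite statistics excluded:", x$n_nonfinite_excluded, "\n")
  }
  invisible(x)
}

#' Genomic-control F-test p-value recalibration
#'
#' Divides the score statistic by `lambda_m` and refers it to the upper tail
#' of F(1, `df2`) instead of chi-squared(1); the finite second degree of
#' freedom yields slightly heavier-tailed (more conservative) p-values, and
#' `df2 = Inf` recovers the chi-squared(1) tail exactly.
#'
#' @param stat score statistic(s), >= 0.
#' @param lambda_m genomic-control inflation factor, > 0.
#' @param df2 denominator degrees of freedom, default 100.
#' @return recalibrated p-value(s).
#' @export
gcf_adjust <- function(stat, lambda_m, df2 = 100) {
  stopifnot(all(stat >= 0, na.rm = TRUE), lambda_m > 0, df2 > 0)
  x <- stat / lambda_m
  if (is.infinite(df2)) {
    stats::pchisq(x, df = 1, lower.tail = FALSE)
  } else {
    stats::pf(x, df1 = 1, df2 = df2, lower.tail = FALSE)
  }
}

#' Quantile-quantile plot data for a set of p-values
#'
#' Pairs the i-th smallest observed `-log10(p)` with the expected uniform
#' quantile `-log10((i - 0.5) / n)` and reports the genomic-control lambda
#' computed from all statistics via the median rule.
#'
#' @param pvalues p-values in (0, 1]; zeros are rejected.
#' @return list with `points` (`data.frame`: `expected`, `observed`, both on
#'   the -log10 scale, monotonically paired) and `lambda` (a
#'   `lambda_estimate` when >= 100 p-values are supplied, otherwise `NA`).
#' @export
qq_data <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  n <- length(pvalues)
  i <- seq_len(n)
  points <- data.frame(expected = -log10((i - 0.5) / n),
                       observed = -log10(sort(pvalues)))
  lam <- if (n >= 100) {
    estimate_lambda_median(stats::qchisq(pvalues, df = 1, lower.tail = FALSE))
  } else NA
  list(points = points, lambda = lam)
}
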