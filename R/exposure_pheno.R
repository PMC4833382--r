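#' Scale a vector by its interquartile range
#'
#' Distance exposures are analysed per IQR unit, so a one-unit change in the
#' scaled exposure corresponds to an IQR-meter change in raw distance.
#' Quartiles use linear interpolation (type-7, the R default).
#'
#' @param values numeric vector (meters); at least 4 finite values.
#' @return list with `scaled` (values / IQR) and `iqr` (Q3 - Q1, meters).
#' @export
iqr_scale <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need at least 4 finite values to estimate an IQR")
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr <= 0) stop("IQR is zero; exposure cannot be scaled")
  list(scaled = values / iqr, iqr = iqr)
}

#' Continuity-corrected chi-squared test for a 2x2 table
#'
#' Pearson chi-squared with the Yates correction
#' `sum((|O - E| - c)^2 / E)`, `c = min(0.5, |O - E|)`, referred to the
#' upper tail of chi-squared with 1 df.  Used for the binary covariates of
#' cohort summary tables.
#'
#' @param counts 2x2 matrix of non-negative counts (rows = groups,
#'   columns = outcome yes/no), or a length-4 vector filled by row.
#' @param correct apply the continuity correction (default TRUE).
#' @return list with `statistic`, `p.value`, `df`.
#' @export
chisq_yates <- function(counts, correct = TRUE) {
  x <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  if (!all(dim(x) == c(2, 2))) stop("counts must form a 2x2 table")
  if (any(x < 0)) stop("counts must be non-negative")
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  expd <- outer(rs, cs) / n
  d <- abs(x - expd)
  cc <- if (correct) pmin(0.5, d) else 0
  stat <- sum((d - cc)^2 / expd)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' One-way fixed-effects ANOVA F test
#'
#' Thin wrapper over `stats::oneway.test(var.equal = TRUE)` for the
#' continuous covariates of cohort summary tables.
#'
#' @param groups list of (>= 2) numeric vectors, each of length >= 2.
#' @return list with `statistic` (F), `p.value`, `df` = c(k-1, N-k).
#' @export
anova_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need a list of >= 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("zero within-group variance in every group; F undefined")
  }
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  res <- stats::oneway.test(y ~ f, var.equal = TRUE)
  list(statistic = unname(res$statistic),
       p.value = res$p.value,
       df = unname(res$parameter))
}

#' Cohort characteristics table
#'
#' Per-stratum n, mean (SD) for continuous covariates, count (percent) for
#' binary covariates, with cross-stratum p-values from [anova_f()]
#' (continuous) and [chisq_yates()] (binary, two strata).  Percentages are
#' rounded to three significant digits as conventionally printed.  Missing
#' covariate values are excluded cell-wise.
#'
#' @param frame sample-frame `data.frame` with a `stratum` column.
#' @param variables covariate columns to summarise; defaults to every numeric
#'   column except identifiers and the exposure scaling artifacts.
#' @return `data.frame` with one row per (variable, statistic), columns
#'   `variable`, `type`, `overall`, one column per stratum, and `p` (omitted
#'   for a single-stratum frame).
#' @export
summarize_cohort <- function(frame, variables = NULL) {
  stopifnot("stratum" %in% names(frame))
  strata <- unique(frame$stratum)
  if (is.null(variables)) {
    drop <- c("sample_id", "stratum", "distance_m", "exposure_scaled")
    variables <- setdiff(names(frame)[vapply(frame, is.numeric, logical(1))],
                         drop)
  }
  is_binary <- vapply(variables, function(v) {
    u <- unique(frame[[v]][!is.na(frame[[v]])])
    all(u %in% c(0, 1))
  }, logical(1))

  fmt_cont <- function(x) {
    x <- x[!is.na(x)]
    sprintf("%s (%s)", signif(mean(x), 3), signif(stats::sd(x), 3))
  }
  fmt_bin <- function(x) {
    x <- x[!is.na(x)]
    sprintf("%d (%s)", sum(x), signif(100 * mean(x), 3))
  }
  rows <- lapply(seq_along(variables), function(i) {
    v <- variables[i]
    x <- frame[[v]]
    fmt <- if (is_binary[i]) fmt_bin else fmt_cont
    per <- vapply(strata, function(s) fmt(x[frame$stratum == s]), character(1))
    p <- NA_real_
    if (length(strata) > 1) {
      if (is_binary[i]) {
        if (length(strata) == 2) {
          tab <- vapply(strata, function(s) {
            xs <- x[frame$stratum == s & !is.na(x)]
            c(sum(xs), sum(1 - xs))
          }, numeric(2))
          p <- chisq_yates(t(tab))$p.value
        } else {
          groups <- lapply(strata, function(s) x[frame$stratum == s & !is.na(x)])
          p <- anova_f(groups)$p.value  # multi-group binary: F on indicators
        }
      } else {
        groups <- lapply(strata, function(s) x[frame$stratum == s & !is.na(x)])
        p <- anova_f(groups)$p.value
      }
    }
    out <- data.frame(variable = v,
                      type = if (is_binary[i]) "binary" else "continuous",
                      overall = fmt(x), stringsAsFactors = FALSE)
    for (s in seq_along(strata)) out[[paste0("stratum_", strata[s])]] <- per[s]
    out$p <- p
    out
  })
  res <- do.call(rbind, rows)
  n_row <- data.frame(variable = "n", type = "count",
                      overall = as.character(nrow(frame)),
                      stringsAsFactors = FALSE)
  for (s in strata) {
    n_row[[paste0("stratum_", s)]] <- as.character(sum(frame$stratum == s))
  }
  n_row$p <- NA_real_
  res <- rbind(n_row, res)
  if (length(strata) < 2) res$p <- NULL
  rownames(res) <- NULL
  res
}
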