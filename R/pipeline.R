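#' Configuration for a full interaction-scan pipeline run
#'
#' Collects the generator settings, model specification, and every analysis
#' threshold so a run is fully determined by one object (plus its seed).
#'
#' @param sim a [sim_config()] describing the synthetic cohort (or the data
#'   a run should emulate).
#' @param spec a [model_spec()].
#' @param outdir output directory; created if absent.
#' @param genome_wide,suggestive,replication significance thresholds.
#' @param maf_min stage-1 per-stratum MAF filter.
#' @param maf_floor minimal polymorphism required to fit a model at all;
#'   variants between `maf_floor` and `maf_min` are fitted but only used
#'   under the relaxed-MAF meta-analysis rule.
#' @param snp_callrate,subject_callrate QC call-rate thresholds.
#' @param se_max interaction-SE filter.
#' @param gcf_df2 denominator df for the genomic-control F recalibration.
#' @param lambda_subsample number of statistics subsampled for lambda;
#'   `NULL` uses all.
#' @param adjust_only_inflated recalibrate a stratum only when its lambda
#'   exceeds 1 (default TRUE).
#' @param seed run seed; defaults to the generator's.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), spec = model_spec(), outdir,
                       genome_wide = 5e-8, suggestive = 1e-5,
                       replication = 0.05, maf_min = 0.05, maf_floor = 0.01,
                       snp_callrate = 0.98, subject_callrate = 0.98,
                       se_max = 10, gcf_df2 = 100, lambda_subsample = NULL,
                       adjust_only_inflated = TRUE, seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"), inherits(spec, "model_spec"),
            genome_wide > 0, genome_wide < 1, suggestive > 0, suggestive < 1,
            replication > 0, replication < 1,
            maf_min >= 0, maf_min <= 0.5, maf_floor >= 0, maf_floor <= maf_min,
            se_max > 0, gcf_df2 > 0)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, spec = spec, outdir = outdir,
                 genome_wide = genome_wide, suggestive = suggestive,
                 replication = replication, maf_min = maf_min,
                 maf_floor = maf_floor, snp_callrate = snp_callrate,
                 subject_callrate = subject_callrate, se_max = se_max,
                 gcf_df2 = gcf_df2, lambda_subsample = lambda_subsample,
                 adjust_only_inflated = adjust_only_inflated,
                 seed = as.integer(seed)),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(err) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(err),
         call. = FALSE)
  })
}

#' Run the full simulate-QC-scan-adjust-meta-stability pipeline
#'
#' Executes the stages in fixed order, writing one TSV (or VCF) per stage
#' plus a manifest with an MD5 checksum for every output file.  Rerunning
#' with an identical config reproduces byte-identical outputs.
#'
#' Stage files: `genotypes.vcf`, `samples.tsv`, `qc_report.tsv`,
#' `scan_results.tsv` (with recalibrated `p_adjusted` where applicable),
#' `lambda.tsv`, `meta_results.tsv`, `stability.tsv`; plus `manifest.tsv`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the stage outputs in memory (`panel`,
#'   `frame`, `qc`, `scan`, `lambda`, `meta`, `stability`, `classified`) and
#'   the `manifest` data.frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  panel <- .stage("simulate", simulate_genotypes(config$sim))
  frame <- .stage("simulate", simulate_phenotypes(panel, config$sim))
  stratum <- attr(panel, "stratum")
  write_vcf(panel, file.path(outdir, "genotypes.vcf"))
  .write_tsv(frame, file.path(outdir, "samples.tsv"))

  qc <- .stage("qc", apply_qc(panel, config$snp_callrate,
                              config$subject_callrate,
                              maf_min = config$maf_floor))
  # QC can drop subjects; keep the stratum attribute aligned for the scan
  attr(qc$panel, "stratum") <- stratum[match(qc$panel$subjects, panel$subjects)]
  write_qc_report(qc$report, file.path(outdir, "qc_report.tsv"))

  scan <- .stage("scan", run_scan(qc$panel, frame, config$spec,
                                  maf_min = config$maf_floor,
                                  genome_wide = config$genome_wide,
                                  suggestive = config$suggestive,
                                  se_max = config$se_max))
  scan$maf_pass <- scan$maf >= config$maf_min

  lambda_rows <- list()
  for (s in unique(scan$stratum)) {
    i <- which(scan$stratum == s & scan$maf_pass & scan$converged)
    if (length(i) < 100) {
      # too few statistics for a stable median; leave the stratum unadjusted
      lambda_rows[[s]] <- data.frame(stratum = s, lambda_m = NA_real_,
                                     n_stats_used = length(i),
                                     adjusted = FALSE,
                                     gcf_df2 = config$gcf_df2)
      next
    }
    lam <- .stage("adjust", estimate_lambda_median(
      scan$stat_T[i], subsample_size = config$lambda_subsample,
      seed = config$seed))
    do_adjust <- lam$lambda_m > 1 || !config$adjust_only_inflated
    if (do_adjust) {
      j <- which(scan$stratum == s & !is.na(scan$stat_T))
      scan$p_adjusted[j] <- gcf_adjust(scan$stat_T[j], lam$lambda_m,
                                       df2 = config$gcf_df2)
    }
    lambda_rows[[s]] <- data.frame(stratum = s, lambda_m = lam$lambda_m,
                                   n_stats_used = lam$n_stats_used,
                                   adjusted = do_adjust,
                                   gcf_df2 = config$gcf_df2)
  }
  lambda_df <- do.call(rbind, lambda_rows)
  rownames(lambda_df) <- NULL
  .write_tsv(lambda_df, file.path(outdir, "lambda.tsv"))

  # stage-1 tags respect the strict MAF filter and the recalibrated p
  p_final <- ifelse(is.na(scan$p_adjusted), scan$p_raw, scan$p_adjusted)
  scan$tag <- ifelse(!scan$maf_pass | is.na(p_final), "",
                     ifelse(p_final < config$genome_wide, "genome_wide",
                            ifelse(p_final < config$suggestive, "suggestive",
                                   "")))
  .write_tsv(scan, file.path(outdir, "scan_results.tsv"))

  meta <- .stage("meta", {
    rows <- lapply(split(seq_len(nrow(scan)), scan$snp), function(i) {
      recs <- scan[i, , drop = FALSE]
      if (nrow(recs) >= 2) {
        al <- align_alleles(
          list(snp = recs$snp[1], effect_allele = recs$effect_allele[1],
               other_allele = recs$other_allele[1], beta = recs$beta_gxe[1],
               maf = recs$maf[1]),
          list(snp = recs$snp[2], effect_allele = recs$effect_allele[2],
               other_allele = recs$other_allele[2], beta = recs$beta_gxe[2],
               maf = recs$maf[2]))
        recs$beta_gxe[2] <- al$b$beta
        recs$effect_allele <- al$effect_allele
      }
      inverse_variance_meta(
        data.frame(snp = recs$snp, effect_allele = recs$effect_allele,
                   cohort = recs$stratum, beta = recs$beta_gxe,
                   se = recs$se_gxe, maf = recs$maf,
                   stringsAsFactors = FALSE),
        maf_min = config$maf_min)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(match(out$snp, scan$snp)), , drop = FALSE]
  })
  .write_tsv(meta, file.path(outdir, "meta_results.tsv"))

  stability <- .stage("stability", {
    top <- scan[scan$tag %in% c("suggestive", "genome_wide") & scan$converged, ,
                drop = FALSE]
    if (nrow(top) == 0) {
      data.frame(snp = character(), stratum = character(),
                 outliers_removed = integer(), or_before = numeric(),
                 or_after = numeric(), p_before = numeric(),
                 p_after = numeric(), stable = logical(),
                 se_filter_pass = logical(), reason = character(),
                 stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_len(nrow(top)), function(r) {
        s <- top$stratum[r]
        sel <- which(attr(qc$panel, "stratum") == s)
        sub_frame <- frame[match(qc$panel$subjects[sel], frame$sample_id), ]
        e <- iqr_scale(sub_frame$distance_m)$scaled
        covs <- as.matrix(sub_frame[, config$spec$covariates, drop = FALSE])
        g <- qc$panel$dosages[sel, top$snp[r]]
        if (mean(g, na.rm = TRUE) / 2 > 0.5) g <- 2L - g
        v <- stability_screen(g, e, sub_frame$outcome, covs,
                              snp_id = top$snp[r], se_max = config$se_max)
        v$stratum <- s
        v
      })
      do.call(rbind, rows)
    }
  })
  .write_tsv(stability, file.path(outdir, "stability.tsv"))

  classified <- classify_hits(scan[scan$maf_pass, , drop = FALSE], meta,
                              genome_wide = config$genome_wide,
                              suggestive = config$suggestive,
                              replication = config$replication)

  manifest <- .write_manifest(outdir)
  invisible(list(panel = panel, frame = frame, qc = qc, scan = scan,
                 lambda = lambda_df, meta = meta, stability = stability,
                 classified = classified, manifest = manifest,
                 outdir = outdir))
}

.write_manifest <- function(outdir) {
  files <- sort(setdiff(list.files(outdir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    bytes = unname(file.size(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  manifest
}

#' Render Manhattan/QQ data files and top-hit tables for a completed run
#'
#' Writes plain-data files a plotting layer can consume: `manhattan.tsv`
#' (chrom, pos, snp, stratum, -log10 p, with the genome-wide and suggestive
#' threshold lines recorded as `#` metadata), one `qq_<stratum>.tsv` per
#' stratum, and `top_hits.tsv` / `meta_top.tsv` shaped like published
#' interaction-hit tables.  The manifest is refreshed to cover the new
#' files.  An empty scan yields empty-but-valid (header-only) reports.
#'
#' @param run_dir output directory of a completed [run_pipeline()] run.
#' @param genome_wide,suggestive threshold metadata written into the files.
#' @return invisibly, the paths written.
#' @export
render_reports <- function(run_dir, genome_wide = 5e-8, suggestive = 1e-5) {
  scan_path <- file.path(run_dir, "scan_results.tsv")
  if (!file.exists(scan_path)) stop("no scan_results.tsv under ", run_dir)
  scan <- utils::read.delim(scan_path, stringsAsFactors = FALSE)
  p_final <- ifelse(is.na(scan$p_adjusted), scan$p_raw, scan$p_adjusted)

  man_path <- file.path(run_dir, "manhattan.tsv")
  con <- file(man_path, "w")
  writeLines(c(sprintf("# genome_wide_line\t%g", genome_wide),
               sprintf("# suggestive_line\t%g", suggestive)), con)
  ok <- !is.na(p_final)
  man <- data.frame(chrom = scan$chrom[ok], pos = scan$pos[ok],
                    snp = scan$snp[ok], stratum = scan$stratum[ok],
                    neglog10_p = -log10(p_final[ok]))
  utils::write.table(man, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  qq_paths <- character(0)
  for (s in unique(scan$stratum)) {
    p <- p_final[scan$stratum == s]
    p <- p[!is.na(p)]
    qq_path <- file.path(run_dir, paste0("qq_", s, ".tsv"))
    if (length(p) > 0) {
      .write_tsv(qq_data(p)$points, qq_path)
    } else {
      .write_tsv(data.frame(expected = numeric(), observed = numeric()),
                 qq_path)
    }
    qq_paths <- c(qq_paths, qq_path)
  }

  top_cols <- c("chrom", "pos", "snp", "stratum", "maf", "or_gxe", "se_gxe",
                "p_raw", "p_adjusted", "tag")
  top <- scan[scan$tag != "" & !is.na(scan$tag), top_cols, drop = FALSE]
  top <- top[order(ifelse(is.na(top$p_adjusted), top$p_raw, top$p_adjusted)), ]
  top_path <- .write_tsv(top, file.path(run_dir, "top_hits.tsv"))

  meta_path <- file.path(run_dir, "meta_results.tsv")
  meta_top_path <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    mt <- meta[!is.na(meta$p_meta), , drop = FALSE]
    mt <- mt[order(mt$p_meta), , drop = FALSE]
    mt <- utils::head(mt, 20)
    meta_top_path <- .write_tsv(mt, file.path(run_dir, "meta_top.tsv"))
  }
  .write_manifest(run_dir)
  invisible(c(man_path, qq_paths, top_path, meta_top_path))
}
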