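#' Genotype panel container
#'
#' A `genotype_panel` bundles an additive-dosage matrix with its variant
#' metadata and sample identifiers.  Dosages are minor/alt-allele counts in
#' \{0, 1, 2\} with `NA` for missing calls, subjects in rows and variants in
#' columns — the orientation every per-SNP regression in the scan consumes.
#'
#' @param dosages numeric or integer matrix, subjects x variants, entries in
#'   \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `chrom`, `pos` (1-based, strictly
#'   increasing within a chromosome), `id` (unique), `ref`, `alt`.
#' @param subjects character vector of sample ids; defaults to
#'   `rownames(dosages)`.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `variants`, `subjects`.
#' @export
genotype_panel <- function(dosages, variants, subjects = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(subjects)) {
    subjects <- sprintf("S%04d", seq_len(nrow(dosages)))
  }
  subjects <- as.character(subjects)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL

  need <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols) > 0) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variant table rows (", nrow(variants), ") do not match dosage columns (",
         ncol(dosages), ")")
  }
  if (length(subjects) != nrow(dosages)) {
    stop("subject ids (", length(subjects), ") do not match dosage rows (",
         nrow(dosages), ")")
  }
  if (anyDuplicated(variants$id)) {
    dup <- unique(variants$id[duplicated(variants$id)])
    stop("duplicate variant id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  bad_dom <- dosages[!is.na(dosages)]
  if (length(bad_dom) > 0 && !all(bad_dom %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  dimnames(dosages) <- list(subjects, variants$id)
  structure(list(dosages = dosages, variants = variants, subjects = subjects),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$subjects), "subjects x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  chromosomes: %s; missing calls: %.3f%%\n",
              paste(unique(x$variants$chrom), collapse = ", "), 100 * miss))
  invisible(x)
}

#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$subjects)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  genotype_panel(x$dosages[i, j, drop = FALSE],
                 x$variants[j, , drop = FALSE],
                 x$subjects[i])
}

#' Number of subjects / variants in a panel
#' @param panel a `genotype_panel`
#' @return integer count
#' @export
n_subjects <- function(panel) length(panel$subjects)

#' @rdname n_subjects
#' @export
n_variants <- function(panel) nrow(panel$variants)

# GT string -> dosage; anything outside the biallelic GT-only dialect errors.
.gt_to_dosage <- function(gt, ids) {
  gt <- sub(":.*$", "", gt)  # tolerate trailing FORMAT fields
  map <- c("0/0" = 0L, "0|0" = 0L,
           "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
           "1/1" = 2L, "1|1" = 2L)
  out <- unname(map[gt])
  is_miss <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  out[is_miss] <- NA_integer_
  bad <- is.na(out) & !is_miss
  if (any(bad)) {
    stop("malformed GT call(s) at variant(s): ",
         paste(utils::head(unique(ids[which(bad, arr.ind = TRUE)[, 1]]), 5),
               collapse = ", "))
  }
  out
}

#' Read a minimal GT-only VCF into a genotype panel
#'
#' Supports the biallelic, GT-only dialect written by [write_vcf()]:
#' `./.` encodes a missing call and multi-allelic records are rejected.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic record(s) not supported: ",
         paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  ids <- matrix(rep(fix[, "ID"], ncol(gt)), nrow = nrow(gt))
  dos <- matrix(.gt_to_dosage(as.vector(gt), as.vector(ids)),
                nrow = nrow(gt), ncol = ncol(gt))
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"],
                         ref = fix[, "REF"],
                         alt = alt,
                         stringsAsFactors = FALSE)
  genotype_panel(t(dos), variants, subjects = colnames(gt))
}

#' Write a genotype panel as a minimal GT-only VCF
#'
#' @param panel a [genotype_panel()].
#' @param path output path; plain text, one FORMAT field (`GT`), `./.` for
#'   missing calls.  `write_vcf()` followed by [read_vcf()] reproduces the
#'   panel exactly.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  gt_map <- c("0/0", "0/1", "1/1")
  d <- t(panel$dosages)  # variants x subjects
  gt <- matrix(gt_map[d + 1L], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  v <- panel$variants
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$subjects), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Minor allele frequency
#'
#' Alt-allele frequency p is computed over non-missing calls per variant
#' (complete-case per SNP); the MAF is `min(p, 1 - p)`, invariant to which
#' allele is labelled minor.
#'
#' @param panel a [genotype_panel()].
#' @param snp optional variant id(s) or column index(es); default all.
#' @return named numeric vector of MAFs in `[0, 0.5]`; `NA` (with a warning)
#'   for variants with no non-missing calls.
#' @export
maf <- function(panel, snp = NULL) {
  d <- panel$dosages
  if (!is.null(snp)) d <- d[, snp, drop = FALSE]
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  if (any(n == 0)) {
    warning("MAF undefined for all-missing variant(s): ",
            paste(utils::head(colnames(d)[n == 0], 5), collapse = ", "))
  }
  stats::setNames(pmin(p, 1 - p), colnames(d))
}

#' Apply call-rate and MAF quality-control filters
#'
#' Filters are applied in a fixed order: variants by call rate, then subjects
#' by call rate (over the retained variants), then variants by MAF (over the
#' retained subjects).  The MAF boundary is inclusive (`maf >= maf_min`
#' retained).
#'
#' @param panel a [genotype_panel()].
#' @param snp_callrate minimum per-variant call rate, default 0.98.
#' @param subject_callrate minimum per-subject call rate, default 0.98.
#' @param maf_min minimum minor allele frequency, default 0.05.
#' @return list with elements `panel` (filtered) and `report` (`qc_report`:
#'   per-stage removal counts plus the thresholds used).
#' @export
apply_qc <- function(panel, snp_callrate = 0.98, subject_callrate = 0.98,
                     maf_min = 0.05) {
  stopifnot(snp_callrate >= 0, snp_callrate <= 1,
            subject_callrate >= 0, subject_callrate <= 1,
            maf_min >= 0, maf_min <= 0.5)
  d <- panel$dosages
  keep_snp1 <- colMeans(!is.na(d)) >= snp_callrate
  n_snp_cr <- sum(!keep_snp1)
  d1 <- d[, keep_snp1, drop = FALSE]
  keep_subj <- if (ncol(d1) > 0) rowMeans(!is.na(d1)) >= subject_callrate else
    rep(TRUE, nrow(d1))
  n_subj_cr <- sum(!keep_subj)
  p2 <- panel[keep_subj, keep_snp1]
  mafs <- suppressWarnings(maf(p2))
  keep_maf <- !is.na(mafs) & mafs >= maf_min
  n_maf <- sum(!keep_maf)
  out <- p2[, keep_maf]
  if (n_subjects(out) == 0 || n_variants(out) == 0) {
    stop("QC removed every subject or variant; thresholds too strict for this panel")
  }
  report <- structure(list(snps_removed_callrate = n_snp_cr,
                           subjects_removed_callrate = n_subj_cr,
                           snps_removed_maf = n_maf,
                           snps_retained = n_variants(out),
                           subjects_retained = n_subjects(out),
                           thresholds = c(snp_callrate = snp_callrate,
                                          subject_callrate = subject_callrate,
                                          maf_min = maf_min)),
                      class = "qc_report")
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (thresholds: snp callrate", x$thresholds["snp_callrate"],
      ", subject callrate", x$thresholds["subject_callrate"],
      ", MAF >=", x$thresholds["maf_min"], ")\n")
  cat("  variants removed by call rate:", x$snps_removed_callrate, "\n")
  cat("  subjects removed by call rate:", x$subjects_removed_callrate, "\n")
  cat("  variants removed by MAF:      ", x$snps_removed_maf, "\n")
  cat("  retained:", x$subjects_retained, "subjects x", x$snps_retained,
      "variants\n")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [apply_qc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    stage = c("snp_callrate", "subject_callrate", "maf",
              "retained_subjects", "retained_snps"),
    removed = c(report$snps_removed_callrate, report$subjects_removed_callrate,
                report$snps_removed_maf, NA, NA),
    retained = c(NA, NA, NA, report$subjects_retained, report$snps_retained),
    threshold = c(report$thresholds, NA, NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Principal components of standardized genotypes
#'
#' Each variant column is centred at twice its alt-allele frequency and scaled
#' by the binomial standard deviation `sqrt(2 p (1 - p))`; missing calls
#' become 0 after centring (mean imputation on the standardized scale).
#' Scores are the top-`k` left singular vectors scaled by their singular
#' values, with each component's sign fixed so its largest-magnitude variant
#' loading is positive.  Monomorphic variants carry no ancestry information
#' and are excluded with a warning.
#'
#' @param panel a [genotype_panel()], ideally MAF-filtered.
#' @param k number of components; must satisfy
#'   `k < min(n_subjects - 1, n_snps)`.
#' @return numeric matrix, subjects x k, rownames = sample ids.
#' @export
compute_pcs <- function(panel, k) {
  ns <- n_subjects(panel)
  nv <- n_variants(panel)
  if (k < 1 || k >= min(ns - 1, nv)) {
    stop("k must satisfy 1 <= k < min(n_subjects - 1, n_snps) = ",
         min(ns - 1, nv))
  }
  d <- panel$dosages
  n_call <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_call, 1))
  mono <- n_call == 0 | p <= 0 | p >= 1
  if (any(mono)) {
    warning("excluding ", sum(mono), " monomorphic variant(s) from PCA")
    d <- d[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  x <- sweep(d, 2, 2 * p, "-")
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u, 2, sv$d[seq_len(k)] * flip, "*")
  dimnames(scores) <- list(panel$subjects, paste0("PC", seq_len(k)))
  scores
}
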