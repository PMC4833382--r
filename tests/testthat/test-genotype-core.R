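test_that("minimal GT-only VCF reads into the expected dosage matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trsA\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trsB\tC\tT\t.\t.\t.\tGT\t./.\t1/1\t0/0"), path)
  panel <- read_vcf(path)
  expect_equal(dim(panel$dosages), c(3, 2))
  expect_identical(sum(is.na(panel$dosages)), 1L)
  expect_equal(unname(panel$dosages[, "rsA"]), c(0L, 1L, 2L))
  expect_equal(unname(panel$dosages[, "rsB"]), c(NA_integer_, 2L, 0L))
  expect_equal(panel$variants$pos, c(100L, 200L))
  expect_equal(panel$subjects, c("s1", "s2", "s3"))
})

test_that("write-then-read round trip is exact", {
  cfg <- sim_config(n_per_stratum = 40, n_snps = 12, fst = 0, rho = 0,
                    missing_rate = 0.05, seed = 4)
  panel <- simulate_genotypes(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(panel, path)
  back <- read_vcf(path)
  expect_identical(unname(back$dosages), unname(panel$dosages))
  expect_equal(back$variants, panel$variants)
  expect_identical(back$subjects, panel$subjects)
  # second round trip of the re-read panel is byte-stable
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("multi-allelic records are rejected with the offending variant named", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\trsMulti\tA\tG,T\t.\t.\t.\tGT\t0/1"), path)
  expect_error(read_vcf(path), "rsMulti")
})

test_that("panel validation rejects malformed input", {
  d <- matrix(0L, 2, 2)
  v <- data.frame(chrom = "1", pos = c(10L, 20L), id = c("a", "b"),
                  ref = "A", alt = "G")
  expect_error(genotype_panel(matrix(3L, 2, 2), v), "dosages")
  v_dup <- v; v_dup$id <- c("a", "a")
  expect_error(genotype_panel(d, v_dup), "duplicate")
  v_pos <- v; v_pos$pos <- c(20L, 10L)
  expect_error(genotype_panel(d, v_pos), "increasing")
})

test_that("maf matches hand counts and flags undefined variants", {
  panel <- make_tiny_panel()
  m <- maf(panel)
  expect_equal(unname(m["v1"]), 3 / 6)    # dosages 0,1,2,NA over 3 calls
  expect_equal(unname(m["v2"]), 0)        # monomorphic
  expect_equal(unname(m["v3"]), 1 / 8)    # 7/8 alt -> minor 1/8
  all_miss <- genotype_panel(matrix(NA_integer_, 3, 1),
                             data.frame(chrom = "1", pos = 1L, id = "m",
                                        ref = "A", alt = "G"),
                             subjects = paste0("s", 1:3))
  expect_warning(mm <- maf(all_miss), "all-missing")
  expect_true(is.na(mm))
})

test_that("maf is invariant to swapping allele labels", {
  cfg <- sim_config(n_per_stratum = 60, n_snps = 30, fst = 0, rho = 0,
                    missing_rate = 0.05, seed = 9)
  panel <- simulate_genotypes(cfg)
  swapped <- panel
  swapped$dosages <- 2L - panel$dosages
  expect_equal(maf(panel), maf(swapped))
})

test_that("QC filters in fixed order with the counts of a constructed fixture", {
  # 100 subjects x 10 variants, built for per-stage removals (2, 1, 3)
  set.seed(42)
  d <- matrix(rbinom(100 * 10, 2, 0.3), 100, 10)
  d[2:4, 1] <- NA                        # SNPs 1-2 fail call rate (97/100)
  d[2:4, 2] <- NA
  d[1, 3] <- NA                          # SNP 3 keeps 99/100, passes; but
                                         # subject 1 drops to 7/8 on the
                                         # retained variants and is removed
  d[, 4] <- 0L                           # three monomorphic SNPs fail MAF
  d[, 5] <- 2L
  d[, 6] <- 0L
  v <- data.frame(chrom = "1", pos = 10L * (1:10),
                  id = sprintf("q%02d", 1:10), ref = "A", alt = "G")
  panel <- genotype_panel(d, v, subjects = sprintf("s%03d", 1:100))
  qc <- apply_qc(panel, snp_callrate = 0.98, subject_callrate = 0.98,
                 maf_min = 0.05)
  expect_equal(qc$report$snps_removed_callrate, 2)
  expect_equal(qc$report$subjects_removed_callrate, 1)
  expect_equal(qc$report$snps_removed_maf, 3)
  expect_equal(n_variants(qc$panel), 5)
  expect_equal(n_subjects(qc$panel), 99)
})

test_that("MAF exactly at the boundary is retained and QC is idempotent", {
  # variant with MAF exactly 0.05: 1 alt allele in 10 subjects
  d <- cbind(c(1L, rep(0L, 9)), rbinom(10, 2, 0.4))
  panel <- genotype_panel(d, data.frame(chrom = "1", pos = c(5L, 6L),
                                        id = c("edge", "common"),
                                        ref = "A", alt = "G"),
                          subjects = sprintf("s%02d", 1:10))
  expect_equal(unname(maf(panel, "edge")), 0.05)
  qc <- apply_qc(panel, maf_min = 0.05)
  expect_true("edge" %in% qc$panel$variants$id)

  cfg <- sim_config(n_per_stratum = 80, n_snps = 40, fst = 0, rho = 0,
                    missing_rate = 0.01, seed = 21)
  sim <- simulate_genotypes(cfg)
  once <- apply_qc(sim)
  twice <- apply_qc(once$panel)
  expect_identical(once$panel$dosages, twice$panel$dosages)
  expect_equal(twice$report$snps_removed_callrate, 0)
  expect_equal(twice$report$subjects_removed_callrate, 0)
  expect_equal(twice$report$snps_removed_maf, 0)
})

test_that("QC errors when nothing survives", {
  d <- matrix(c(0L, 0L, 0L, 0L), 2, 2)  # all monomorphic
  panel <- genotype_panel(d, data.frame(chrom = "1", pos = c(1L, 2L),
                                        id = c("a", "b"), ref = "A",
                                        alt = "G"),
                          subjects = c("s1", "s2"))
  expect_error(apply_qc(panel), "thresholds too strict")
})

test_that("PC1 separates simulated ancestry strata", {
  cfg <- sim_config(n_per_stratum = c(150, 100), n_snps = 300, fst = 0.1,
                    rho = 0, missing_rate = 0, seed = 3)
  panel <- simulate_genotypes(cfg)
  scores <- compute_pcs(panel, 2)
  lab <- as.integer(factor(attr(panel, "stratum")))
  expect_gt(abs(cor(scores[, 1], lab)), 0.9)
})

test_that("PC scores are orthogonal and duplicated subjects score identically", {
  cfg <- sim_config(n_per_stratum = 60, n_snps = 80, fst = 0, rho = 0,
                    missing_rate = 0, seed = 6)
  panel <- simulate_genotypes(cfg)
  dup <- genotype_panel(panel$dosages[c(1:60, 1), ],
                        panel$variants,
                        subjects = c(panel$subjects, "dup_of_1"))
  scores <- compute_pcs(dup, 3)
  expect_equal(scores["dup_of_1", ], scores[1, ])
  gram <- crossprod(scores)
  expect_lt(max(abs(gram[upper.tri(gram)])) / max(diag(gram)), 1e-8)
})

test_that("compute_pcs enforces its dimension bound", {
  d <- matrix(c(0L, 1L, 1L, 2L, 0L, 1L), 2, 3)
  panel <- genotype_panel(d, data.frame(chrom = "1", pos = c(1L, 2L, 3L),
                                        id = c("a", "b", "c"),
                                        ref = "A", alt = "G"),
                          subjects = c("s1", "s2"))
  expect_error(compute_pcs(panel, 1), "k must satisfy")
})
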