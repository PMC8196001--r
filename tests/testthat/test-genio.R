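test_that("GT calls parse to dosages and EAF", {
  path <- write_toy_vcf(vcf_record(calls = c("0/0", "0/1", "1/1")))
  g <- read_vcf(path)
  expect_equal(unname(g$dosage[, 1]), c(0, 1, 2))
  expect_equal(g$variants$eaf, 0.5)
  expect_equal(g$samples, c("S1", "S2", "S3"))
})

test_that("DS dosages parse as given with fractional EAF", {
  path <- write_toy_vcf(
    vcf_record(format_id = "DS", calls = c("0.1", "0.9", "1.7")),
    format_id = "DS")
  g <- read_vcf(path)
  expect_equal(unname(g$dosage[, 1]), c(0.1, 0.9, 1.7))
  expect_equal(g$variants$eaf, 2.7 / 6)
})

test_that("multiallelic records are rejected, others survive", {
  path <- write_toy_vcf(c(
    vcf_record(pos = 100, id = "rs1"),
    vcf_record(pos = 200, id = "rs2", alt = "G,T",
               calls = c("0/0", "0/1", "1/2")),
    vcf_record(pos = 300, id = "rs3")))
  expect_warning(g <- read_vcf(path), "multiallelic")
  expect_equal(g$variants$id, c("rs1", "rs3"))
})

test_that("malformed VCF reports the offending line number", {
  path <- write_toy_vcf(c(
    vcf_record(pos = 100, id = "rs1"),
    "1\t200\trs2\tA"))
  expect_error(read_vcf(path), "line 5")
})

test_that("missing genotypes are mean-imputed; all-missing variants dropped", {
  path <- write_toy_vcf(c(
    vcf_record(pos = 100, id = "rs1", calls = c("0/0", "./.", "1/1")),
    vcf_record(pos = 200, id = "rs2", calls = c("./.", "./.", "./."))))
  expect_warning(g <- read_vcf(path), "missing in all samples")
  expect_equal(g$variants$id, "rs1")
  expect_equal(unname(g$dosage[, 1]), c(0, 1, 2)) # imputed to mean of 0,2
  expect_equal(unname(attr(g, "missingness")["rs1"]), 1 / 3)
})

test_that("info scores are read from INFO and used by filter_variants", {
  path <- write_toy_vcf(c(
    vcf_record(pos = 100, id = "rs1", info = "INFO=0.2"),
    vcf_record(pos = 200, id = "rs2", info = "INFO=0.3"),
    vcf_record(pos = 300, id = "rs3", info = "INFO=0.9")))
  g <- read_vcf(path)
  expect_equal(g$variants$info, c(0.2, 0.3, 0.9))
  kept <- filter_variants(g, maf_min = 0, info_min = 0.3)
  expect_equal(kept$variants$id, c("rs2", "rs3")) # boundary inclusive
})

test_that("filter_variants applies the MAF threshold and preserves order", {
  set.seed(11)
  n <- 1000
  D <- cbind(rbinom(n, 2, 0.005), rbinom(n, 2, 0.02), rbinom(n, 2, 0.49))
  # force exact EAFs via direct construction
  mk <- function(eaf) { x <- numeric(n); x[seq_len(round(2 * n * eaf))] <- 1; x }
  D <- cbind(mk(0.005), mk(0.02), mk(0.49))
  g <- genotype_matrix(D, data.frame(chrom = "1", pos = 1:3 * 100,
                                     id = paste0("v", 1:3),
                                     ref = "A", alt = "G"))
  expect_equal(filter_variants(g, maf_min = 0)$variants$id, g$variants$id)
  expect_equal(filter_variants(g, maf_min = 0.01)$variants$id, c("v2", "v3"))
})

test_that("VCF write/read round-trips hard calls and dosages", {
  co <- quick_cohort(n = 40, m = 12, seed = 5)
  path <- tempfile(fileext = ".vcf")
  write_vcf(co$genotypes, path)
  g2 <- read_vcf(path)
  expect_equal(g2$dosage, co$genotypes$dosage)
  expect_equal(g2$variants$id, co$genotypes$variants$id)
  # fractional dosages go through DS
  gd <- co$genotypes
  gd$dosage[1, 1] <- 0.25
  gd <- genotype_matrix(gd$dosage, gd$variants[, 1:5], gd$samples)
  path2 <- tempfile(fileext = ".vcf")
  write_vcf(gd, path2)
  g3 <- read_vcf(path2)
  expect_equal(g3$dosage[1, 1], 0.25, tolerance = 1e-6)
})

test_that("summary statistics round-trip losslessly and validate columns", {
  res <- data.frame(chrom = "2", pos = c(1e6, 2e6, 3e6, 4e6, 5e6),
                    id = paste0("rs", 1:5), ea = "T", oa = "C",
                    eaf = runif(5), beta = rnorm(5) / 3,
                    se = runif(5, 0.01, 0.1), p = 10^(-runif(5, 1, 54)))
  path <- tempfile(fileext = ".tsv")
  write_summary_stats(res, path)
  back <- read_summary_stats(path)
  for (col in c("eaf", "beta", "se", "p"))
    expect_equal(back[[col]], res[[col]], tolerance = 1e-14)
  expect_error(write_summary_stats(res[, -7], path), "beta")
})

test_that("phenotype IO validates required columns and handles empty tables", {
  co <- quick_cohort(n = 30, m = 5, seed = 9)
  path <- tempfile(fileext = ".tsv")
  write_phenotypes(co$phenotypes, path)
  back <- read_phenotypes(path)
  expect_equal(back$bilirubin, co$phenotypes$bilirubin, tolerance = 1e-14)
  # missing required column is a named error
  broken <- co$phenotypes
  broken$hypertension <- NULL
  path2 <- tempfile(fileext = ".tsv")
  data.table::fwrite(broken, path2, sep = "\t")
  expect_error(read_phenotypes(path2), "hypertension")
  # 0-row table remains valid
  empty <- co$phenotypes[0, ]
  path3 <- tempfile(fileext = ".tsv")
  write_phenotypes(empty, path3)
  expect_equal(nrow(read_phenotypes(path3)), 0)
})

test_that("stored EAF always matches EAF recomputed from dosages", {
  co <- quick_cohort(n = 150, m = 60, seed = 13)
  g <- co$genotypes
  expect_equal(g$variants$eaf, unname(colMeans(g$dosage) / 2),
               tolerance = 1e-12)
  expect_error(genotype_matrix(g$dosage,
                               transform(g$variants[, 1:5],
                                         id = rep("dup", 60))),
               "duplicate")
})
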