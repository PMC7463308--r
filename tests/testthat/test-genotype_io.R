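# Genotype containers, file round-trips and the locus filters.

test_that("VCF parsing maps genotypes and missing calls", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           paste(c("r1", "10", "snp1", "A", "T", ".", "PASS", ".", "GT",
                   "0/0", "0/1", "1/1"), collapse = "\t"),
           paste(c("r2", "5", "snp2", "G", "C", ".", "PASS", ".", "GT",
                   "./.", "1/1", "0/0"), collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  m <- load_genotypes(f, "vcf")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m$genotypes)), 1L)
  expect_equal(unname(m$genotypes[, "snp1"]), c(0L, 1L, 2L))
  expect_equal(rownames(m$genotypes), c("s1", "s2", "s3"))
  expect_equal(m$radlocus, c("r1", "r2"))
})

test_that("multiallelic records are rejected", {
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1"), collapse = "\t"),
           paste(c("r1", "1", "x", "A", "T,G", ".", ".", ".", "GT", "0/1"),
                 collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_error(load_genotypes(f, "vcf"), "multiallelic")
})

test_that("write/load round-trips preserve the matrix in both formats", {
  set.seed(1)
  g <- matrix(sample(c(0:2, NA), 24, replace = TRUE), 4,
              dimnames = list(paste0("s", 1:4), paste0("snp", 1:6)))
  g[1, colSums(!is.na(g)) == 0] <- 0L
  m <- snp_matrix(g, radlocus_ids = rep(c("r1", "r2", "r3"), each = 2),
                  pos = rep(c(4L, 9L), 3))
  for (fmt in c("table", "vcf")) {
    f <- withr::local_tempfile()
    write_genotypes(m, f, fmt)
    m2 <- load_genotypes(f, fmt)
    expect_equal(m2$genotypes, m$genotypes, ignore_attr = FALSE)
  }
})

test_that("table and VCF input give the same matrix", {
  g <- matrix(c(0L, 1L, 2L, NA, 2L, 0L, 1L, 1L, 0L, 0L, 2L, 2L), 4,
              dimnames = list(paste0("s", 1:4), paste0("snp", 1:3)))
  m <- snp_matrix(g)
  fv <- withr::local_tempfile(); ft <- withr::local_tempfile()
  write_genotypes(m, fv, "vcf")
  write_genotypes(m, ft, "table")
  expect_equal(load_genotypes(fv, "vcf")$genotypes,
               load_genotypes(ft, "table")$genotypes)
})

test_that("snp_matrix validates entries, ids and empty columns", {
  expect_error(snp_matrix(matrix(3L, 2, 1)), "0, 1, 2 or NA")
  expect_error(snp_matrix(matrix(0L, 2, 2,
                                 dimnames = list(NULL, c("a", "a")))),
               "unique")
  expect_error(snp_matrix(matrix(NA_integer_, 2, 1)), "non-missing")
})

test_that("within-population presence rule keeps/drops per hand enumeration", {
  # two populations of 5; need ceil(0.6*5) = 3 calls per pop
  pm <- toy_pmap(2, 5)
  nl <- 10
  set.seed(2)
  g <- matrix(1L, 10, nl, dimnames = list(pm$sample, paste0("L", 1:nl)))
  # per-locus calls in pop1 and pop2 by construction:
  calls1 <- c(5, 3, 2, 5, 4, 0, 3, 5, 1, 3)
  calls2 <- c(5, 5, 5, 2, 3, 5, 3, 4, 5, 2)
  for (l in seq_len(nl)) {
    g[seq_len(5 - calls1[l]), l] <- NA
    g[5 + seq_len(5 - calls2[l]), l] <- NA
  }
  g[, 6][1] <- 1L  # keep at least one call for validity (locus still < 3 in pop1)
  m <- snp_matrix(g)
  kept <- locus_ids(filter_within_pop_presence(m, pm, 0.6))
  # hand enumeration: both pops need >= 3 calls
  expect_equal(kept, paste0("L", c(1, 2, 5, 7, 8)))
  # a locus with no missing data survives any threshold
  expect_true("L1" %in% kept)
})

test_that("sample-coverage filter counts calls and nests across thresholds", {
  set.seed(3)
  g <- matrix(sample(c(0:2, NA, NA), 6 * 12, replace = TRUE), 6,
              dimnames = list(paste0("s", 1:6), paste0("L", 1:12)))
  g[1, colSums(!is.na(g)) == 0] <- 1L
  m <- snp_matrix(g)
  kept4 <- locus_ids(filter_sample_coverage(m, 4))
  expect_equal(kept4, colnames(g)[colSums(!is.na(g)) >= 4])
  expect_equal(locus_ids(filter_sample_coverage(m, 1)), locus_ids(m))
  # monotone containment mirrors the strict/median/lenient dataset ladder
  k6 <- locus_ids(filter_sample_coverage(m, 6))
  k5 <- locus_ids(filter_sample_coverage(m, 5))
  expect_true(all(k6 %in% k5) && all(k5 %in% kept4))
})

test_that("MAF filter drops rare and monomorphic loci, keeps ties", {
  # 171 diploids, one heterozygote -> MAF 1/342 < 0.01
  g <- matrix(0L, 171, 3, dimnames = list(NULL, c("mono", "rare", "ok")))
  g[1, "rare"] <- 1L
  g[1:20, "ok"] <- 1L
  m <- snp_matrix(g)
  expect_equal(locus_ids(filter_maf(m, 0.01)), "ok")
  expect_equal(locus_ids(filter_maf(m, 0)), c("mono", "rare", "ok"))
  # exact tie kept: MAF = threshold
  g2 <- matrix(c(rep(0L, 9), 2L), 10, 1, dimnames = list(NULL, "tie"))
  expect_equal(locus_ids(filter_maf(snp_matrix(g2), 0.1)), "tie")
})

test_that("one SNP per RAD locus retains the first by position", {
  g <- matrix(1L, 3, 7, dimnames = list(NULL, paste0("s", 1:7)))
  m <- snp_matrix(g, radlocus_ids = c("r1", "r1", "r1", "r2", "r3", "r3",
                                      "r4"),
                  pos = c(30L, 10L, 20L, 1L, 2L, 1L, 5L))
  out <- one_snp_per_radlocus(m)
  expect_equal(ncol(out$genotypes), 4L)
  expect_true(all(c("s2", "s4", "s6", "s7") %in% locus_ids(out)))
  # all-distinct RAD loci: identity
  m2 <- snp_matrix(g)
  expect_equal(locus_ids(one_snp_per_radlocus(m2)), locus_ids(m2))
  # random rule is deterministic under a seed
  set.seed(9); a <- locus_ids(one_snp_per_radlocus(m, "random"))
  set.seed(9); b <- locus_ids(one_snp_per_radlocus(m, "random"))
  expect_equal(a, b)
})

test_that("filters are idempotent and commute with sample reordering", {
  set.seed(4)
  pm <- toy_pmap(2, 4)
  g <- matrix(sample(c(0:2, NA), 8 * 20, replace = TRUE), 8,
              dimnames = list(pm$sample, paste0("L", 1:20)))
  g[1, colSums(!is.na(g)) == 0] <- 1L
  m <- snp_matrix(g)
  f1 <- filter_maf(m, 0.1)
  expect_equal(filter_maf(f1, 0.1)$genotypes, f1$genotypes)
  f2 <- filter_within_pop_presence(m, pm, 0.6)
  expect_equal(filter_within_pop_presence(f2, pm, 0.6)$genotypes,
               f2$genotypes)
  # reorder samples, filter, restore order: same locus set
  ord <- sample(nrow(g))
  mo <- snp_matrix(g[ord, ])
  expect_equal(locus_ids(filter_within_pop_presence(mo, pm, 0.6)),
               locus_ids(f2))
  # any filter's locus set is a subset of its input's
  expect_true(all(locus_ids(f1) %in% locus_ids(m)))
})
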