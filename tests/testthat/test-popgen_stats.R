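# Diversity, pairwise PhiST and AMOVA against hand arithmetic and the
# brute-force distance-enumeration oracle.

test_that("diversity matches the unbiased estimator by hand", {
  # two diploids, genotypes 0 and 2: p = 0.5 over n = 4 genes
  g <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "L1"))
  pm <- pop_map(c("a", "b"), c("P", "P"), c("G", "G"), c(0, 0), c(0, 0))
  d <- diversity(snp_matrix(g), pm, min_n = 2)
  expect_equal(d$Hexp, 2 * 0.25 * (4 / 3))
  expect_equal(d$pi, 2 / 3)
  expect_equal(d$Hobs, 0)
  # all heterozygous: Hobs = 1 at the locus
  g2 <- matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "L1"))
  pm2 <- pop_map(c("a", "b", "c"), rep("P", 3), rep("G", 3), rep(1, 3), rep(1, 3))
  expect_equal(diversity(snp_matrix(g2), pm2, min_n = 3)$Hobs, 1)
  # monomorphic population
  g3 <- matrix(2L, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(diversity(snp_matrix(g3), pm2, min_n = 3)$pi, 0)
  expect_equal(diversity(snp_matrix(g3), pm2, min_n = 3)$Hexp, 0)
})

test_that("small populations are excluded with a warning, not an error", {
  pm <- toy_pmap(2, 3)
  set.seed(5)
  g <- matrix(sample(0:2, 6 * 4, TRUE), 6,
              dimnames = list(pm$sample, paste0("L", 1:4)))
  expect_warning(d <- diversity(snp_matrix(g), pm, min_n = 5), "excluding")
  expect_equal(nrow(d), 0)
})

test_that("pairwise PhiST hits the analytic anchors", {
  set.seed(6)
  pm <- toy_pmap(2, 10)
  # both populations drawn from the same allele frequencies: PhiST ~ 0
  pl <- runif(500, 0.2, 0.8)
  g <- counts_to_geno(cbind(rbinom(500, 20, pl), rbinom(500, 20, pl)), 10)
  ph <- pairwise_phist(snp_matrix(g), pm)
  expect_lt(abs(ph[1, 2]), 0.02)
  # fixed difference at all loci: PhiST = 1
  g2 <- cbind(matrix(c(rep(0L, 10), rep(2L, 10)), 20, 5))
  rownames(g2) <- pm$sample
  ph2 <- pairwise_phist(snp_matrix(g2), pm)
  expect_equal(ph2[1, 2], 1)
})

test_that("2-pop PhiST equals the brute-force oracle on a small fixture", {
  set.seed(7)
  pm <- toy_pmap(2, 4)
  g <- matrix(sample(0:2, 8 * 3, TRUE), 8,
              dimnames = list(pm$sample, paste0("L", 1:3)))
  m <- snp_matrix(g)
  ph <- pairwise_phist(m, pm)
  pop <- factor(pm$population)
  orc <- oracle_amova(g, pop)
  expect_equal(ph[1, 2], unname(orc$phi["phi_ST"]), tolerance = 1e-12)
})

test_that("AMOVA components match the oracle to 1e-10 with missing data", {
  set.seed(8)
  pm <- toy_pmap(4, 5, groups = c("G1", "G1", "G2", "G2"))
  g <- matrix(sample(c(0:2, NA), 20 * 20, TRUE, prob = c(.3, .3, .3, .1)),
              20, dimnames = list(pm$sample, paste0("L", 1:20)))
  g[1, colSums(!is.na(g)) == 0] <- 1L
  m <- snp_matrix(g)
  am <- amova(m, pm, levels = 3, n_perm = 0)
  orc <- oracle_amova(g, factor(pm$population), factor(pm$group))
  expect_equal(am$sigma2, orc$sigma2, tolerance = 1e-10)
  expect_equal(am$phi, orc$phi, tolerance = 1e-10)
  # two-level as well
  am2 <- amova(m, pm, levels = 2, n_perm = 0)
  orc2 <- oracle_amova(g, factor(pm$population))
  expect_equal(am2$sigma2, orc2$sigma2, tolerance = 1e-10)
})

test_that("pairwise PhiST equals AMOVA restricted to the pair", {
  set.seed(9)
  pm <- toy_pmap(3, 4)
  g <- matrix(sample(0:2, 12 * 10, TRUE), 12,
              dimnames = list(pm$sample, paste0("L", 1:10)))
  m <- snp_matrix(g)
  ph <- pairwise_phist(m, pm)
  sel <- pm$population %in% c("P1", "P3")
  m2 <- snp_matrix(g[sel, ])
  am <- amova(m2, pm[sel, ], levels = 2, n_perm = 0)
  expect_equal(ph["P1", "P3"], unname(am$phi["phi_ST"]), tolerance = 1e-12)
})

test_that("AMOVA is invariant to allele relabeling (0<->2 swap)", {
  set.seed(10)
  pm <- toy_pmap(3, 4, groups = c("G1", "G1", "G2"))
  g <- matrix(sample(0:2, 12 * 15, TRUE), 12,
              dimnames = list(pm$sample, paste0("L", 1:15)))
  am1 <- amova(snp_matrix(g), pm, levels = 3, n_perm = 0)
  am2 <- amova(snp_matrix(2L - g), pm, levels = 3, n_perm = 0)
  expect_equal(am1$sigma2, am2$sigma2, tolerance = 1e-12)
})

test_that("degenerate AMOVA anchors: one pop errors, fixed groups give Phi_CT = 1", {
  pm1 <- toy_pmap(1, 4)
  g1 <- matrix(sample(0:2, 4 * 5, TRUE), 4,
               dimnames = list(pm1$sample, paste0("L", 1:5)))
  am1 <- amova(snp_matrix(g1), pm1, levels = 2)
  expect_equal(unname(am1$phi["phi_ST"]), 0)
  expect_match(am1$flags, "undefined")
  # two groups, one population each, fixed difference
  pm2 <- toy_pmap(2, 5, groups = c("G1", "G2"))
  g2 <- matrix(c(rep(0L, 5), rep(2L, 5)), 10, 4,
               dimnames = list(pm2$sample, paste0("L", 1:4)))
  am <- amova(snp_matrix(g2), pm2, levels = 3, n_perm = 0)
  expect_equal(unname(am$phi["phi_CT"]), 1)
})

test_that("permutation p-values are small under structure, calibrated under the null", {
  set.seed(11)
  pm <- toy_pmap(2, 8)
  # strong structure: p must be at the resolution floor
  g <- cbind(matrix(c(rep(0L, 8), rep(2L, 8)), 16, 10))
  rownames(g) <- pm$sample
  am <- amova(snp_matrix(g), pm, levels = 2, n_perm = 99)
  expect_equal(unname(am$p_value["phi_ST"]), 1 / 100)
  # exchangeable null: p approximately uniform (KS on 60 panmictic reps)
  set.seed(12)
  ps <- replicate(60, {
    gg <- counts_to_geno(matrix(rbinom(40, 16, 0.4), 20, 2), 8)
    # both pops drawn from one pool: relabel rows randomly
    gg <- gg[sample(nrow(gg)), ]
    rownames(gg) <- pm$sample
    amova(snp_matrix(gg), pm, levels = 2,
          n_perm = 59)$p_value[["phi_ST"]]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("diversity-geography regression matches the closed form", {
  set.seed(13)
  n <- 22
  coords <- data.frame(population = paste0("P", 1:n),
                       lat = runif(n, 20, 40), lon = runif(n, 90, 140))
  vals <- setNames(0.2 + 0.01 * coords$lon + rnorm(n, 0, 0.05),
                   coords$population)
  res <- diversity_gradient(vals, coords, "lon")
  r_hand <- sum((vals - mean(vals)) * (coords$lon - mean(coords$lon))) /
    sqrt(sum((vals - mean(vals))^2) * sum((coords$lon - mean(coords$lon))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  # exactly linear response: |r| = 1, p ~ 0
  vexact <- setNames(coords$lon * 2, coords$population)
  rex <- diversity_gradient(vexact, coords, "lon")
  expect_equal(rex$r, 1)
  expect_lt(rex$p, 1e-10)
  # constant response flagged degenerate with r = 0
  rc <- diversity_gradient(setNames(rep(1, n), coords$population), coords,
                           "lat")
  expect_true(rc$degenerate)
  expect_equal(rc$r, 0)
  expect_error(diversity_gradient(vals, transform(coords, lat = 1), "lat"),
               "zero variance")
})
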