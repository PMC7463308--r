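# Scenario specification, prior sampling and the coalescent SNP simulator,
# checked against a naive pure-R coalescent and its analytic limits.

two_pop_spec <- function(t_split, sizes = c(A = 1000, B = 1000), nd = 10) {
  scenario_spec("two", c("A", "B"), c(A = nd, B = nd),
                c(A = "NA_", B = "NB"),
                data.frame(time = as.character(t_split), type = "merge",
                           a = "B", b = "A", c = NA, x = NA,
                           stringsAsFactors = FALSE),
                data.frame(param = c("NA_", "NB"),
                           lo = unname(sizes), hi = unname(sizes)))
}

test_that("prior draws respect bounds, constraints and degenerate priors", {
  sc <- builtin_scenarios()$divergence$S2
  set.seed(20)
  draws <- t(replicate(2000, sample_prior(sc)))
  for (k in seq_len(nrow(sc$priors)))
    expect_true(all(draws[, sc$priors$param[k]] >= sc$priors$lo[k] &
                      draws[, sc$priors$param[k]] <= sc$priors$hi[k]))
  expect_true(all(draws[, "t1"] > draws[, "t2"]))
  # degenerate prior is constant
  sp <- two_pop_spec(1000)
  expect_equal(unname(sample_prior(sp)["NA_"]), 1000)
  # unsatisfiable constraint errors
  bad <- scenario_spec("bad", "A", c(A = 2), c(A = "N"),
                       data.frame(time = "10", type = "resize", a = "A",
                                  b = NA, c = NA, x = "N",
                                  stringsAsFactors = FALSE),
                       data.frame(param = c("N", "u"), lo = c(1, 5),
                                  hi = c(4, 6)),
                       data.frame(larger = "N", smaller = "u"))
  expect_error(sample_prior(bad, max_tries = 50), "unsatisfiable")
})

test_that("builtin scenarios validate and carry the published priors", {
  sc <- builtin_scenarios()
  for (s in c(sc$divergence, sc$demography))
    expect_true(validate_scenario(s))
  s2 <- sc$divergence$S2
  expect_setequal(s2$priors$param,
                  c("NA_anc", "NSW", "NCE", "NJP", "t1", "t2"))
  expect_equal(s2$priors$lo[s2$priors$param == "NA_anc"], 10)
  expect_equal(s2$priors$hi[s2$priors$param == "NA_anc"], 1e6)
  expect_equal(s2$priors$lo[s2$priors$param == "t1"], 100)
  expect_equal(s2$priors$hi[s2$priors$param == "t1"], 5e7)
  expect_equal(s2$priors$hi[s2$priors$param == "t2"], 1e7)
  expect_equal(s2$priors$hi[s2$priors$param == "NCE"], 1.6e6)
  d3 <- sc$demography$D3
  expect_setequal(d3$priors$param,
                  c("Na", "N2", "Nb", "N1", "t3", "tb", "t4"))
})

test_that("scenario JSON round-trips", {
  sc <- builtin_scenarios()$divergence$S5
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(sc2$priors, sc$priors)
  expect_equal(sc2$events$type, sc$events$type)
  expect_equal(sc2$n_diploid, sc$n_diploid)
})

test_that("sample heterozygosity matches the naive coalescent oracle", {
  # one panmictic population; compare mean heterozygosity (2p(1-p) over the
  # sample) of SNP-conditioned loci against an independently coded O(n^2)
  # gene-tree simulation
  set.seed(21)
  nd <- 6; N <- 5000; nl <- 2000
  sp <- scenario_spec("one", "A", c(A = nd), c(A = "N"),
                      data.frame(time = character(0), type = character(0),
                                 a = character(0), b = character(0),
                                 c = character(0), x = character(0)),
                      data.frame(param = "N", lo = N, hi = N))
  m <- simulate_snps(sp, sample_prior(sp), nl)
  p_imp <- colMeans(m$genotypes) / 2
  het_imp <- 2 * p_imp * (1 - p_imp)
  cnt <- naive_snp_counts(2 * nd, N, nl)
  p_orc <- cnt / (2 * nd)
  het_orc <- 2 * p_orc * (1 - p_orc)
  se <- sqrt(var(het_imp) / nl + var(het_orc) / nl)
  expect_lt(abs(mean(het_imp) - mean(het_orc)), 3 * se)
  # full site-frequency spectra should agree too (chi-squared sanity)
  tab_i <- tabulate(colSums(m$genotypes), 2 * nd - 1)
  tab_o <- tabulate(cnt, 2 * nd - 1)
  expect_gt(suppressWarnings(
    chisq.test(cbind(tab_i, tab_o))$p.value), 0.001)
})

test_that("split-time limits: panmixia and deep divergence", {
  set.seed(22)
  pmv <- scenario_popmap(two_pop_spec(1))
  m0 <- simulate_snps(two_pop_spec(1), sample_prior(two_pop_spec(1)), 1000)
  expect_lt(abs(pairwise_phist(m0, pmv)[1, 2]), 0.02)
  deep <- two_pop_spec(1e6)  # >> 4N = 4000
  m1 <- simulate_snps(deep, sample_prior(deep), 1000)
  expect_gt(pairwise_phist(m1, pmv)[1, 2], 0.9)
})

test_that("S2 with t2 near t1 is indistinguishable from the simultaneous split", {
  set.seed(23)
  sc <- builtin_scenarios()$divergence
  pars <- c(NA_anc = 5e5, NSW = 3e5, NCE = 9e5, NJP = 2.8e5,
            t1 = 5e6, t2 = 5e6 - 1)
  pm <- scenario_popmap(sc$S2)
  s2stats <- t(replicate(40, summarize_snps(
    simulate_snps(sc$S2, pars, 300), pm)))
  s1stats <- t(replicate(40, summarize_snps(
    simulate_snps(sc$S1, pars[names(pars) != "t2"], 300), pm)))
  # two-sample t-tests per summary: none should reject at alpha = 0.01
  # (Bonferroni over the registry)
  ps <- vapply(seq_len(ncol(s2stats)), function(j) {
    if (sd(s2stats[, j]) + sd(s1stats[, j]) == 0) return(1)
    t.test(s2stats[, j], s1stats[, j])$p.value
  }, numeric(1))
  expect_gt(min(p.adjust(ps, "bonferroni")), 0.01)
})

test_that("full admixture collapses the admixed group onto one source", {
  set.seed(24)
  sc <- builtin_scenarios()$divergence
  pars <- c(NA_anc = 5e5, NSW = 3e5, NCE = 9e5, NJP = 2.8e5,
            t1 = 8e6, t2 = 2e6, ra = 0.999)
  pm <- scenario_popmap(sc$S5)
  s5stats <- t(replicate(40, summarize_snps(
    simulate_snps(sc$S5, pars, 300), pm)))
  s2stats <- t(replicate(40, summarize_snps(
    simulate_snps(sc$S2, pars[!names(pars) %in% "ra"], 300), pm)))
  ps <- vapply(seq_len(ncol(s5stats)), function(j) {
    if (sd(s5stats[, j]) + sd(s2stats[, j]) == 0) return(1)
    t.test(s5stats[, j], s2stats[, j])$p.value
  }, numeric(1))
  expect_gt(min(p.adjust(ps, "bonferroni")), 0.01)
})

test_that("individual exchangeability within groups", {
  set.seed(25)
  sc <- two_pop_spec(5000, nd = 8)
  pm <- scenario_popmap(sc)
  m <- simulate_snps(sc, sample_prior(sc), 400)
  s1 <- summarize_snps(m, pm)
  # permute individuals within each population: identical summaries
  g <- m$genotypes
  ord <- c(sample(1:8), 8 + sample(1:8))
  g2 <- g[ord, ]
  rownames(g2) <- rownames(g)
  expect_equal(summarize_snps(snp_matrix(g2), pm), s1)
})

test_that("masking respects the rate and keeps loci callable", {
  set.seed(26)
  sc <- two_pop_spec(1000)
  m <- simulate_snps(sc, sample_prior(sc), 500)
  mm <- mask_missing(m, 0.2)
  expect_equal(mean(is.na(mm$genotypes)), 0.2, tolerance = 0.03)
  expect_true(all(colSums(!is.na(mm$genotypes)) >= 1))
  expect_identical(mask_missing(m, 0)$genotypes, m$genotypes)
})
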