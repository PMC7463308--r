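# Summary statistics, reference tables, scenario choice and local-linear
# parameter estimation.

test_that("summary vector matches hand arithmetic on a tiny fixture", {
  g <- matrix(c(0L, 2L, 1L, 1L,   # locus 1
                0L, 0L, 2L, 2L,   # locus 2
                0L, 0L, 0L, 1L,   # locus 3
                2L, 2L, 2L, 2L,   # locus 4 (monomorphic overall)
                1L, 0L, 0L, 0L),  # locus 5
              nrow = 4,
              dimnames = list(c("a1", "a2", "b1", "b2"), paste0("L", 1:5)))
  pm <- pop_map(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"),
                c("A", "A", "B", "B"), rep(1, 4), rep(1, 4))
  s <- summarize_snps(snp_matrix(g), pm)
  # group A: counts d = (2,0,0,4,1) over n = 4 genes
  dA <- c(2, 0, 0, 4, 1) / 4
  hA <- 2 * dA * (1 - dA) * 4 / 3
  expect_equal(unname(s["mono_A"]), 3 / 5)
  expect_equal(unname(s["hdiv_A"]), mean(hA))
  expect_equal(unname(s["vdiv_A"]), var(hA))
  # pooled pair monomorphic: only L4
  expect_equal(unname(s["monop_A_B"]), 1 / 5)
  # Hudson FST (ratio of averages) by hand
  pA <- dA; pB <- c(2, 4, 1, 4, 0) / 4
  num <- (pA - pB)^2 - pA * (1 - pA) / 3 - pB * (1 - pB) / 3
  den <- pA * (1 - pB) + pB * (1 - pA)
  expect_equal(unname(s["fst_A_B"]), sum(num) / sum(den))
  # Nei distance by hand
  jx <- mean(pA^2 + (1 - pA)^2); jy <- mean(pB^2 + (1 - pB)^2)
  jxy <- mean(pA * pB + (1 - pA) * (1 - pB))
  expect_equal(unname(s["nei_A_B"]), -log(jxy / sqrt(jx * jy)))
})

test_that("summary anchors: monomorphic group and identical groups", {
  g <- matrix(c(0L, 0L, 0L, 1L), 2,
              dimnames = list(c("a1", "b1"), c("L1", "L2")))
  pm <- pop_map(c("a1", "b1"), c("A", "B"), c("A", "B"), c(1, 1), c(1, 1))
  s <- summarize_snps(snp_matrix(g), pm)
  expect_equal(unname(s["mono_A"]), 1)
  expect_equal(unname(s["hdiv_A"]), 0)
  # two identical groups: FST ~ 0
  set.seed(30)
  gg <- counts_to_geno(cbind(rbinom(100, 10, 0.5), rbinom(100, 10, 0.5)), 5)
  pm2 <- toy_pmap(2, 5, groups = c("GA", "GB"))
  s2 <- summarize_snps(snp_matrix(gg), pm2)
  expect_lt(abs(s2["fst_GA_GB"]), 0.05)
})

test_that("reference tables have the right shape and reproduce under a seed", {
  sc <- builtin_scenarios()$divergence[c("S1", "S2")]
  nd <- c(SW = 4, CE = 4, JP = 4)
  sc <- lapply(sc, function(s) { s$n_diploid <- nd; s })
  set.seed(31)
  ref <- build_reference(sc, 10, 50)
  expect_equal(nrow(ref$sumstats), 20)
  expect_equal(as.vector(table(ref$scenario)), c(10, 10))
  expect_true(all(is.na(ref$params$t2[ref$scenario == "S1"])))
  set.seed(31)
  ref2 <- build_reference(sc, 10, 50)
  expect_identical(ref$sumstats, ref2$sumstats)
  expect_identical(ref$params, ref2$params)
})

test_that("model choice: symmetry, separability and the tolerance-1 limit", {
  # two scenarios with identical generative process -> probabilities ~ 1/2
  set.seed(32)
  n <- 2500
  Z <- matrix(rnorm(2 * n * 3), ncol = 3)
  colnames(Z) <- c("s1", "s2", "s3")
  ref <- structure(list(
    scenario = factor(rep(c("A", "B"), each = n)),
    params = data.frame(th = runif(2 * n)),
    sumstats = Z, specs = NULL, n_loci = NA,
    registry = colnames(Z)), class = "rg_reference")
  obs <- c(s1 = 0, s2 = 0, s3 = 0)
  post <- model_posterior(ref, obs, tolerance = 1, method = "rejection")
  expect_equal(unname(post$prob), c(0.5, 0.5), tolerance = 1e-12)
  post2 <- model_posterior(ref, obs, tolerance = 0.2, method = "mnlogit")
  expect_equal(unname(post2$prob["A"]), 0.5, tolerance = 0.06)
  expect_equal(sum(post2$prob), 1)
  # separable scenarios: winner > 0.95
  Z2 <- Z; Z2[ref$scenario == "B", ] <- Z2[ref$scenario == "B", ] + 8
  ref2 <- ref; ref2$sumstats <- Z2
  p3 <- model_posterior(ref2, obs, tolerance = 0.2, method = "mnlogit")
  expect_gt(p3$prob["A"], 0.95)
  # rejection at tolerance 1 recovers prior frequencies even when unbalanced
  sel <- c(1:n, n + 1:(n / 4))
  ref3 <- ref
  ref3$scenario <- ref$scenario[sel]
  ref3$sumstats <- ref$sumstats[sel, ]
  ref3$params <- ref$params[sel, , drop = FALSE]
  p4 <- model_posterior(ref3, obs, tolerance = 1, method = "rejection")
  expect_equal(unname(p4$prob), c(0.8, 0.2), tolerance = 1e-12)
  # Bayes factors consistent with probabilities
  expect_equal(unname(p4$bayes_factors["A", "B"]), 4, tolerance = 1e-9)
})

test_that("cross-validation confusion matrix bookkeeping", {
  set.seed(33)
  n <- 600
  Z <- matrix(rnorm(2 * n * 2), ncol = 2)
  colnames(Z) <- c("s1", "s2")
  ref <- structure(list(
    scenario = factor(rep(c("A", "B"), each = n)),
    params = data.frame(th = runif(2 * n)),
    sumstats = Z, specs = NULL, n_loci = NA,
    registry = colnames(Z)), class = "rg_reference")
  cv <- cv_model_selection(ref, 25, tolerance = 0.2)
  expect_equal(sum(cv$confusion), 50)
  expect_equal(unname(rowSums(cv$confusion)), c(25, 25))
  # identically distributed scenarios: rate ~ 0.5
  expect_lt(abs(cv$rate - 0.5), 0.2)
  expect_error(cv_model_selection(ref, n + 1), "exceeds")
})

# a linear single-scenario reference: theta uniform, summaries are noisy or
# noise-free linear functions of theta
linear_ref <- function(n, k_par = 2, noise = 0, seed = 1) {
  set.seed(seed)
  th <- matrix(runif(n * k_par, 1, 3), n)
  colnames(th) <- paste0("p", seq_len(k_par))
  S <- cbind(th[, 1] + rnorm(n, 0, noise),
             if (k_par > 1) th[, 2] + rnorm(n, 0, noise) else NULL,
             rnorm(n))
  colnames(S) <- paste0("s", seq_len(ncol(S)))
  spec <- list(name = "lin",
               priors = data.frame(param = colnames(th), lo = 1, hi = 3))
  structure(list(scenario = factor(rep("lin", n)),
                 params = as.data.frame(th), sumstats = S,
                 specs = list(lin = spec), n_loci = NA,
                 registry = colnames(S)),
            class = "rg_reference")
}

test_that("rejection posterior at tolerance 1 reproduces the prior", {
  ref <- linear_ref(4000, 1, noise = 10)
  pe <- estimate_params(ref, c(s1 = 2, s2 = 0), tolerance = 1,
                        regression = "none")
  expect_equal(pe$median, 2, tolerance = 0.05)
  expect_equal(pe$q2.5, 1 + 0.025 * 2, tolerance = 0.05)
  expect_equal(pe$q97.5, 3 - 0.025 * 2, tolerance = 0.05)
})

test_that("loclinear collapses on the truth for noise-free linear summaries", {
  ref <- linear_ref(3000, 2, noise = 0)
  obs <- c(s1 = 1.8, s2 = 2.4, s3 = 0)
  pe <- estimate_params(ref, obs, tolerance = 0.05,
                        regression = "loclinear", transform = "none")
  expect_equal(pe$median[pe$parameter == "p1"], 1.8, tolerance = 0.02)
  expect_equal(pe$median[pe$parameter == "p2"], 2.4, tolerance = 0.02)
  spread <- pe$q97.5 - pe$q2.5
  expect_true(all(spread < 0.02))   # < 1% of the prior range
  # always inside the prior support (logit guarantee)
})

test_that("posterior estimates respect prior bounds even for extreme observations", {
  ref <- linear_ref(2000, 1, noise = 0.05)
  pe <- estimate_params(ref, c(s1 = 10, s2 = 0), tolerance = 0.05)
  expect_true(all(pe$q2.5 >= 1 & pe$q97.5 <= 3 &
                    pe$median >= 1 & pe$median <= 3))
})

test_that("cv_estimation errors are ~1 for noise and ~0 for linear summaries", {
  ref_noise <- linear_ref(1500, 1, noise = 50, seed = 3)
  set.seed(34)
  e1 <- cv_estimation(ref_noise, 40, tolerances = 0.1,
                      methods = "rejection")
  expect_equal(e1$error, 1, tolerance = 0.4)
  ref_lin <- linear_ref(1500, 1, noise = 0, seed = 4)
  set.seed(35)
  e2 <- cv_estimation(ref_lin, 40, tolerances = 0.1, methods = "loclinear")
  expect_lt(e2$error, 0.05)
  expect_true(all(is.finite(e1$error)) && all(e1$error >= 0))
})

test_that("PCA model check flags displaced observations", {
  set.seed(36)
  S <- matrix(rnorm(1000 * 3), ncol = 3)
  colnames(S) <- paste0("s", 1:3)
  ref <- structure(list(scenario = factor(rep("A", 1000)),
                        params = data.frame(th = runif(1000)),
                        sumstats = S, specs = NULL, n_loci = NA,
                        registry = colnames(S)), class = "rg_reference")
  centre <- colMeans(S)
  chk <- model_check_pca(ref, observed = centre)
  expect_true(chk$inside_prior)
  far <- centre + 10 * apply(S, 2, sd)
  chk2 <- model_check_pca(ref, observed = far)
  expect_false(chk2$inside_prior)
  # rank order of distances to the centroid is preserved by the projection
  pts <- S[1:50, ]
  full_d <- sqrt(rowSums(sweep(pts, 2, centre)^2))
  proj <- model_check_pca(ref, posterior_draws = pts, observed = centre)
  proj_d <- sqrt(rowSums(sweep(proj$posterior_coords, 2,
                               colMeans(chk$prior_coords))^2))
  expect_gt(cor(full_d, proj_d, method = "spearman"), 0.7)
})

test_that("generation-time conversion is linear", {
  expect_equal(generations_to_years(6.39e5), 6.39e6)
  expect_equal(generations_to_years(0), 0)
  a <- runif(1, 0, 1e6); b <- runif(1, 0, 1e6)
  expect_equal(generations_to_years(a + b),
               generations_to_years(a) + generations_to_years(b))
  expect_equal(generations_to_years(100, generation_time = 25), 2500)
})

test_that("standardization makes scenario choice invariant to summary rescaling", {
  set.seed(37)
  n <- 800
  Z <- matrix(rnorm(2 * n * 2), ncol = 2)
  Z[(n + 1):(2 * n), 1] <- Z[(n + 1):(2 * n), 1] + 2
  colnames(Z) <- c("s1", "s2")
  ref <- structure(list(scenario = factor(rep(c("A", "B"), each = n)),
                        params = data.frame(th = runif(2 * n)),
                        sumstats = Z, specs = NULL, n_loci = NA,
                        registry = colnames(Z)), class = "rg_reference")
  obs <- c(s1 = 1, s2 = 0)
  p1 <- model_posterior(ref, obs, tolerance = 0.2, method = "rejection")
  ref2 <- ref
  ref2$sumstats[, 1] <- ref2$sumstats[, 1] * 1000
  p2 <- model_posterior(ref2, c(s1 = 1000, s2 = 0), tolerance = 0.2,
                        method = "rejection")
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
})
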