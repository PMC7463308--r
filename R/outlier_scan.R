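# FST outlier scans: a Bayesian FST-decomposition scan (reversible-jump
# MCMC over locus effects) and an island-model simulation scan conditioning
# on heterozygosity, plus their intersection.

# per-locus Weir-Cockerham-style components from pop allele counts
wc_fst_terms <- function(d, n) {
  # d, n: pops x loci derived counts and gene counts
  p <- ifelse(n > 0, d / n, NA)
  r <- colSums(n > 0)
  nbar <- colSums(n) / r
  pbar <- colSums(ifelse(n > 0, n * p, 0)) / colSums(n)
  s2 <- colSums(ifelse(n > 0, n * sweep(p, 2, pbar)^2, 0)) /
    ((r - 1) * nbar)
  nc <- (colSums(n) - colSums(n^2) / colSums(n)) / (r - 1)
  hbar <- 2 * pbar * (1 - pbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- pbar * (1 - pbar) + (r - 1) / r * s2 - a * nc / nbar
  # a/(a+b) is the FST of the frequency model (no within-individual level)
  list(a = a, b = b, het = hbar)
}

pop_allele_counts <- function(m, pmap) {
  pop <- match_pops(m, pmap)
  cnt <- count_by(m$genotypes, pop)
  cnt
}

# multi-locus pi-based Hudson FST: 1 - mean(within-pop diversity) /
# mean(between-pop diversity); unbiased for the island-model pairwise-time
# FST, so the migration tuning of the null is exact under this estimator
hudson_fst_global <- function(d, n) {
  p <- ifelse(n > 0, d / n, NA)
  piw <- colMeans(ifelse(n > 1, 2 * p * (1 - p) * n / pmax(n - 1, 1), NA),
                  na.rm = TRUE)
  npop <- nrow(d)
  pb <- 0; np2 <- 0
  for (i in seq_len(npop - 1)) for (j in (i + 1):npop) {
    pb <- pb + p[i, ] * (1 - p[j, ]) + p[j, ] * (1 - p[i, ])
    np2 <- np2 + 1
  }
  1 - mean(piw, na.rm = TRUE) / mean(pb / np2, na.rm = TRUE)
}

#' Bayesian FST-decomposition outlier scan
#'
#' Decomposes locus-population FST into a locus effect (alpha) and a
#' population effect (beta) on the logistic scale,
#' `FST_ij = plogis(alpha_i + beta_j)`, with population allele frequencies
#' integrated out (beta-binomial likelihood). A reversible-jump move toggles
#' each alpha against a point mass at zero with the given prior odds for
#' neutrality. Loci are ranked by the posterior probability that alpha is in
#' the model; q-values are the running mean of `1 - prob` down that ranking.
#' A locus is flagged when `q < q_threshold` and its posterior mean alpha is
#' positive (diversifying selection).
#'
#' @param m a [snp_matrix()].
#' @param pmap a [pop_map()].
#' @param prior_odds prior odds for the neutral model (default 10).
#' @param n_iter posterior samples kept.
#' @param thin sweeps between kept samples.
#' @param n_pilot,pilot_len pilot runs used to adapt proposal scales.
#' @param burnin additional burn-in sweeps.
#' @param sd_alpha prior SD of included locus effects.
#' @param q_threshold flagging threshold on the q-value.
#' @return An `rg_outliers` data frame: locus, fst, alpha, beta-adjusted
#'   posterior inclusion probability `prob`, `q`, `flag`.
#' @export
bayescan_scan <- function(m, pmap, prior_odds = 10, n_iter = 5000, thin = 20,
                          n_pilot = 20, pilot_len = 5000, burnin = 50000,
                          sd_alpha = 1, q_threshold = 0.001) {
  if (nlevels(match_pops(m, pmap)) < 2) stop("need at least 2 populations")
  cnt <- pop_allele_counts(m, pmap)
  a <- t(cnt$d); nm <- t(cnt$n)           # loci x pops
  res <- rg_bayescan_mcmc(a, nm, prior_odds, as.integer(n_iter),
                          as.integer(thin), as.integer(n_pilot),
                          as.integer(pilot_len), as.integer(burnin),
                          sd_alpha)
  if (any(res$acc < 0.1 | res$acc > 0.6, na.rm = TRUE))
    warning(sprintf(
      "MCMC acceptance rates outside [0.1, 0.6] after pilots (p/alpha/beta: %s)",
      paste(round(res$acc, 2), collapse = "/")))
  wc <- wc_fst_terms(cnt$d, cnt$n)
  fst <- wc$a / (wc$a + wc$b)
  o <- order(res$prob, decreasing = TRUE)
  q <- numeric(length(o))
  q[o] <- cumsum(1 - res$prob[o]) / seq_along(o)
  out <- data.frame(locus = locus_ids(m), fst = fst, alpha = res$alpha,
                    prob = res$prob, q = q,
                    flag = q < q_threshold & res$alpha > 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "beta") <- res$beta
  attr(out, "acceptance") <- res$acc
  class(out) <- c("rg_outliers", "data.frame")
  out
}

#' Island-model simulation outlier scan
#'
#' Estimates the multi-locus global FST from the data, simulates SNP loci
#' under a neutral finite-island coalescent (each sampled population in its
#' own deme among `n_demes_per_pop * n_pops` demes; migration tuned so the
#' island-model expectation matches the target FST), and builds the joint
#' null of (heterozygosity, FST). Each observed locus gets an upper-tail
#' p-value for its FST within its heterozygosity bin (equal-count bins,
#' neighbours pooled below `min_bin` null points); flags are
#' Benjamini-Hochberg at `fdr`. Monomorphic loci are excluded.
#'
#' @param m a [snp_matrix()].
#' @param pmap a [pop_map()].
#' @param n_sims simulated null loci.
#' @param n_demes_per_pop island demes per sampled population.
#' @param fdr false-discovery-rate threshold.
#' @param n_bins heterozygosity bins for the conditional null.
#' @param min_bin minimum null points per (pooled) bin; pooling keeps the
#'   attainable p-value floor `1/(min_bin+1)` low enough for the BH step.
#' @param deme_size diploid deme size (timescale only; the null depends on
#'   the scaled migration rate).
#' @return An `rg_outliers` data frame: locus, fst, het, p, p_adj, flag,
#'   excluded.
#' @export
fdist_scan <- function(m, pmap, n_sims = 20000, n_demes_per_pop = 100,
                       fdr = 0.01, n_bins = 50, min_bin = 5000,
                       deme_size = 1000) {
  cnt <- pop_allele_counts(m, pmap)
  if (nrow(cnt$d) < 2) stop("need at least 2 sampled populations")
  wc <- wc_fst_terms(cnt$d, cnt$n)
  target <- hudson_fst_global(cnt$d, cnt$n)
  if (!is.finite(target) || target <= 0)
    stop("target FST is not positive; island-model null unattainable")
  npop <- nrow(cnt$d)
  D <- n_demes_per_pop * npop
  # island-model pairwise-time FST = 1/(1 + 4 N m D/(D-1))
  mig <- (1 / target - 1) / (4 * deme_size) * (D - 1) / D
  genes <- round(colMeans(t(cnt$n)))          # typical genes per pop
  sim <- rg_sim_island_counts(as.integer(genes), as.integer(D), deme_size,
                              mig, as.integer(n_sims))
  nsim <- matrix(rep(genes, each = n_sims), n_sims)
  simwc <- wc_fst_terms(t(sim), t(nsim))
  null_fst <- simwc$a / (simwc$a + simwc$b)
  null_het <- simwc$het
  keep <- is.finite(null_fst)
  null_fst <- null_fst[keep]; null_het <- null_het[keep]

  obs_fst <- wc$a / (wc$a + wc$b)
  obs_het <- wc$het
  poly <- colSums(cnt$d) > 0 & colSums(cnt$d) < colSums(cnt$n)
  excluded <- !poly | !is.finite(obs_fst)

  # equal-count het bins on the null, neighbour pooling below min_bin
  brks <- unique(quantile(null_het, seq(0, 1, length.out = n_bins + 1)))
  bin_of <- function(h) pmin(pmax(findInterval(h, brks,
                                               rightmost.closed = TRUE), 1),
                             length(brks) - 1)
  nb <- bin_of(null_het)
  p <- rep(NA_real_, n_loci(m))
  for (i in which(!excluded)) {
    b <- bin_of(obs_het[i])
    sel <- nb == b
    lo <- b; hi <- b
    while (sum(sel) < min_bin && (lo > 1 || hi < length(brks) - 1)) {
      lo <- max(1, lo - 1); hi <- min(length(brks) - 1, hi + 1)
      sel <- nb >= lo & nb <= hi
    }
    p[i] <- (sum(null_fst[sel] >= obs_fst[i]) + 1) / (sum(sel) + 1)
  }
  p_adj <- p.adjust(p, "BH")
  out <- data.frame(locus = locus_ids(m), fst = obs_fst, het = obs_het,
                    p = p, p_adj = p_adj,
                    flag = !excluded & !is.na(p_adj) & p_adj <= fdr,
                    excluded = excluded,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "target_fst") <- target
  attr(out, "null") <- data.frame(fst = null_fst, het = null_het)
  class(out) <- c("rg_outliers", "data.frame")
  out
}

#' Intersect outlier calls
#'
#' @param a,b `rg_outliers` results (or anything with `locus` and `flag`
#'   columns).
#' @return Character vector of loci flagged by both scans.
#' @export
intersect_outliers <- function(a, b) {
  intersect(a$locus[a$flag], b$locus[b$flag])
}
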