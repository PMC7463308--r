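# Shared fixtures: small genotype matrices, generators for island-model and
# beta-binomial data, and the brute-force AMOVA oracle used to verify the
# frequency-algebra implementation.

toy_pmap <- function(npop, nd, groups = NULL) {
  pops <- paste0("P", seq_len(npop))
  if (is.null(groups)) groups <- rep("G1", npop)
  pop_map(sample = paste0(rep(pops, each = nd), "_", seq_len(nd)),
          population = rep(pops, each = nd),
          group = rep(groups, each = nd),
          lat = rep(seq_len(npop), each = nd),
          lon = rep(seq_len(npop), each = nd))
}

# derived-count matrix (loci x pops) -> genotype matrix by random pairing
counts_to_geno <- function(cnt, nd, prefix = "L") {
  nl <- nrow(cnt); npop <- ncol(cnt)
  g <- matrix(0L, npop * nd, nl)
  for (p in seq_len(npop)) for (l in seq_len(nl)) {
    genes <- integer(2 * nd)
    if (cnt[l, p] > 0) genes[sample.int(2 * nd, cnt[l, p])] <- 1L
    g[(p - 1) * nd + seq_len(nd), l] <-
      genes[seq(1, 2 * nd, 2)] + genes[seq(2, 2 * nd, 2)]
  }
  rownames(g) <- paste0("P", rep(seq_len(npop), each = nd), "_",
                        rep(seq_len(nd), npop))
  colnames(g) <- paste0(prefix, seq_len(nl))
  g
}

# neutral island-model genotypes at a target FST
island_geno <- function(npop, nd, n_loci, fst = 0.1,
                        n_demes_per_pop = 100) {
  D <- n_demes_per_pop * npop
  mig <- (1 / fst - 1) / (4 * 1000) * (D - 1) / D
  cnt <- relictgen:::rg_sim_island_counts(rep(2L * nd, npop), as.integer(D),
                                          1000, mig, as.integer(n_loci))
  counts_to_geno(cnt, nd)
}

# loci from the logistic FST-decomposition model itself (locus effect alpha)
betabin_loci <- function(n_loci, npop, nd, alpha = 0, beta = qlogis(0.1),
                         prefix = "L") {
  cnt <- matrix(0L, n_loci, npop)
  for (l in seq_len(n_loci)) {
    p <- runif(1, 0.1, 0.9)
    f <- plogis(alpha + beta)
    th <- 1 / f - 1
    pj <- rbeta(npop, th * p, th * (1 - p))
    cnt[l, ] <- rbinom(npop, 2 * nd, pj)
  }
  counts_to_geno(cnt, nd, prefix)
}

# ---- brute-force AMOVA oracle ---------------------------------------------
# Works from explicit gene-by-gene squared distances (allele mismatch) and
# the textbook SSD / expected-mean-square formulas; sums SSD, df and the
# coefficient numerators over loci like the implementation, but computes all
# SSDs by pairwise enumeration.
oracle_amova <- function(g, pop, grp = NULL) {
  nl <- ncol(g)
  ssd_set <- function(x) {
    n <- length(x)
    if (n < 2) return(0)
    tot <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + (x[i] - x[j])^2
    tot / n
  }
  acc <- list(ag = 0, ap = 0, wp = 0, df_ag = 0, df_ap = 0, df_wp = 0,
              n1num = 0, n2num = 0, n3num = 0)
  for (l in seq_len(nl)) {
    keep <- !is.na(g[, l])
    # genotype 0 -> genes (0,0), 1 -> (0,1), 2 -> (1,1)
    genes <- unlist(lapply(g[keep, l], function(x)
      switch(x + 1, c(0, 0), c(0, 1), c(1, 1))))
    gp <- rep(as.character(pop)[keep], each = 2)
    gg <- if (!is.null(grp)) rep(as.character(grp)[keep], each = 2)
    N <- length(genes)
    pops <- unique(gp)
    ssd_t <- ssd_set(genes)
    ssd_wp <- sum(vapply(pops, function(p) ssd_set(genes[gp == p]),
                         numeric(1)))
    np <- vapply(pops, function(p) sum(gp == p), numeric(1))
    if (is.null(grp)) {
      acc$ap <- acc$ap + (ssd_t - ssd_wp)
      acc$wp <- acc$wp + ssd_wp
      acc$df_ap <- acc$df_ap + (length(pops) - 1)
      acc$df_wp <- acc$df_wp + (N - length(pops))
      acc$n1num <- acc$n1num + unname(N - sum(np^2) / N)
    } else {
      grps <- unique(gg)
      ssd_wg <- sum(vapply(grps, function(x) ssd_set(genes[gg == x]),
                           numeric(1)))
      acc$ag <- acc$ag + (ssd_t - ssd_wg)
      acc$ap <- acc$ap + (ssd_wg - ssd_wp)
      acc$wp <- acc$wp + ssd_wp
      acc$df_ag <- acc$df_ag + (length(grps) - 1)
      acc$df_ap <- acc$df_ap + (length(pops) - length(grps))
      acc$df_wp <- acc$df_wp + (N - length(pops))
      ng <- vapply(grps, function(x) sum(gg == x), numeric(1))
      popgrp <- vapply(pops, function(p) gg[gp == p][1], character(1))
      A <- sum(vapply(grps, function(x)
        sum(np[popgrp == x]^2) / ng[[x]], numeric(1)))
      acc$n1num <- acc$n1num + (N - A)
      acc$n2num <- acc$n2num + (A - sum(np^2) / N)
      acc$n3num <- acc$n3num + (N - sum(ng^2) / N)
    }
  }
  acc <- lapply(acc, unname)
  if (is.null(grp)) {
    s2w <- acc$wp / acc$df_wp
    nc <- acc$n1num / acc$df_ap
    s2a <- (acc$ap / acc$df_ap - s2w) / nc
    list(sigma2 = c(among_pops = unname(s2a), within = unname(s2w)),
         phi = c(phi_ST = unname(s2a / (s2a + s2w))))
  } else {
    s2c <- acc$wp / acc$df_wp
    n1 <- acc$n1num / acc$df_ap
    n2 <- acc$n2num / acc$df_ag
    n3 <- acc$n3num / acc$df_ag
    s2b <- (acc$ap / acc$df_ap - s2c) / n1
    s2a <- (acc$ag / acc$df_ag - s2c - n2 * s2b) / n3
    tot <- s2a + s2b + s2c
    list(sigma2 = c(among_groups = unname(s2a),
                    among_pops_within = unname(s2b),
                    within = unname(s2c)),
         phi = c(phi_CT = unname(s2a / tot),
                 phi_SC = unname(s2b / (s2b + s2c)),
                 phi_ST = unname((s2a + s2b) / tot)))
  }
}

# naive single-population coalescent (O(n^2) pair bookkeeping), independent
# of the compiled simulator: returns derived-allele count among n genes for
# one SNP-conditioned locus
naive_snp_counts <- function(n_genes, N, n_loci) {
  vapply(seq_len(n_loci), function(l) {
    nodes <- as.list(seq_len(n_genes))   # each element: vector of leaf ids
    times <- numeric(0)
    t <- 0
    k <- n_genes
    branch_leaves <- list(); branch_len <- numeric(0)
    node_time <- rep(0, n_genes)
    while (k > 1) {
      t <- t + rexp(1, k * (k - 1) / (4 * N))
      pick <- sample.int(k, 2)
      merged <- c(nodes[[pick[1]]], nodes[[pick[2]]])
      for (id in pick) {
        branch_leaves[[length(branch_leaves) + 1]] <- nodes[[id]]
        branch_len <- c(branch_len, t - node_time[id])
      }
      node_time <- c(node_time[-pick], t)
      nodes <- c(nodes[-pick], list(merged))
      k <- k - 1
    }
    b <- sample.int(length(branch_len), 1, prob = branch_len)
    length(branch_leaves[[b]])
  }, numeric(1))
}
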