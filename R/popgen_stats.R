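# Per-population diversity, pairwise PhiST and hierarchical AMOVA.
#
# AMOVA works at the gene (allele) level: each diploid contributes two genes,
# the distance between two genes is the 0/1 allele mismatch, and sums of
# squared deviations reduce to allele-frequency algebra (d derived among n
# genes gives within-set SSD d(n-d)/n). Missing genotypes are dropped
# per locus (pairwise deletion); SSDs, degrees of freedom and the
# coefficients of the expected mean squares are summed over loci before the
# variance components are formed.

# per-locus derived-allele count and gene count by a grouping factor
count_by <- function(g, f) {
  d <- rowsum(ifelse(is.na(g), 0L, g), f)
  n <- rowsum((!is.na(g)) * 2L, f)
  list(d = d, n = n)
}

#' Per-population genetic diversity
#'
#' For each population with at least `min_n` individuals, computes the mean
#' per-SNP nucleotide diversity (`pi`, the unbiased gene diversity
#' `2p(1-p) n/(n-1)` averaged over all loci genotyped in the population),
#' the average expected and observed heterozygosities (`Hexp`/`Hobs`,
#' averaged over the loci polymorphic within the population), with pairwise
#' deletion of missing genotypes. Populations below `min_n` are excluded with
#' a warning.
#'
#' @param m a [snp_matrix()].
#' @param pmap a [pop_map()].
#' @param min_n minimum individuals per retained population.
#' @return Data frame with columns population, n, pi, Hexp, Hobs.
#' @export
diversity <- function(m, pmap, min_n = 5) {
  pop <- match_pops(m, pmap)
  sizes <- table(pop)
  drop <- names(sizes)[sizes < min_n]
  if (length(drop))
    warning("excluding populations below n = ", min_n, ": ",
            paste(drop, collapse = ", "))
  keep <- setdiff(levels(pop), drop)
  cnt <- count_by(m$genotypes, pop)
  het <- rowsum((m$genotypes == 1L) + 0, pop)
  ncall <- rowsum((!is.na(m$genotypes)) + 0, pop)
  out <- lapply(keep, function(p) {
    n <- cnt$n[p, ]; d <- cnt$d[p, ]
    ok <- n >= 2
    pr <- d[ok] / n[ok]
    h <- 2 * pr * (1 - pr) * n[ok] / (n[ok] - 1)
    poly <- d[ok] > 0 & d[ok] < n[ok]
    hobs <- (het[p, ok] / ncall[p, ok])[poly]
    data.frame(population = p, n = as.integer(sizes[p]),
               pi = if (any(ok)) mean(h) else 0,
               Hexp = if (any(poly)) mean(h[poly]) else 0,
               Hobs = if (any(poly)) mean(hobs) else 0)
  })
  if (!length(out))
    return(data.frame(population = character(0), n = integer(0),
                      pi = numeric(0), Hexp = numeric(0),
                      Hobs = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# core SSD/df/coefficient accumulator; pop = factor per individual,
# grp = factor per individual (NULL for 2-level)
amova_components <- function(g, pop, grp = NULL) {
  cnt <- count_by(g, pop)
  d <- cnt$d; n <- cnt$n
  P_l <- colSums(n > 0)
  N_l <- colSums(n)
  D_l <- colSums(d)
  ssd_t <- ifelse(N_l > 0, D_l * (N_l - D_l) / N_l, 0)
  ssd_wp <- colSums(ifelse(n > 0, d * (n - d) / pmax(n, 1), 0))
  if (is.null(grp)) {
    df_ap <- P_l - 1
    df_wp <- N_l - P_l
    ssd_ap <- ssd_t - ssd_wp
    # E[MS_ap] = sigma2_w + nc * sigma2_a
    nc_num <- N_l - colSums(n^2) / N_l
    SSD <- c(ap = sum(ssd_ap), wp = sum(ssd_wp))
    df <- c(ap = sum(df_ap), wp = sum(df_wp))
    nc <- sum(nc_num) / df[["ap"]]
    s2w <- SSD[["wp"]] / df[["wp"]]
    s2a <- (SSD[["ap"]] / df[["ap"]] - s2w) / nc
    list(sigma2 = c(among_pops = s2a, within = s2w),
         SSD = SSD, df = df,
         phi = c(phi_ST = s2a / (s2a + s2w)))
  } else {
    g2p <- tapply(as.character(grp), as.character(pop), function(x) x[1])
    gof <- factor(g2p[rownames(d)], levels = levels(grp))
    dg <- rowsum(d, gof); ng <- rowsum(n, gof)
    G_l <- colSums(ng > 0)
    ssd_g <- colSums(ifelse(ng > 0, dg * (ng - dg) / pmax(ng, 1), 0))
    ssd_ag <- ssd_t - ssd_g
    ssd_ap <- ssd_g - ssd_wp
    df_ag <- G_l - 1
    df_ap <- P_l - G_l
    df_wp <- N_l - P_l
    # coefficients of the expected mean squares (unequal sizes)
    sum_npop2_g <- rowsum(n^2, gof)                  # per group: sum n_p^2
    A <- colSums(ifelse(ng > 0, sum_npop2_g / pmax(ng, 1), 0)) # sum_g sum_p n_p^2/N_g
    B <- colSums(n^2) / N_l                           # sum_p n_p^2 / N
    C <- colSums(ng^2) / N_l                          # sum_g N_g^2 / N
    SSD <- c(ag = sum(ssd_ag), ap = sum(ssd_ap), wp = sum(ssd_wp))
    df <- c(ag = sum(df_ag), ap = sum(df_ap), wp = sum(df_wp))
    n2 <- sum(A - B) / df[["ag"]]
    n3 <- sum(N_l - C) / df[["ag"]]
    s2c <- SSD[["wp"]] / df[["wp"]]
    if (df[["ap"]] > 0) {
      n1 <- sum(N_l - A) / df[["ap"]]
      s2b <- (SSD[["ap"]] / df[["ap"]] - s2c) / n1
    } else s2b <- 0  # one population per group: no within-group level
    s2a <- (SSD[["ag"]] / df[["ag"]] - s2c - n2 * s2b) / n3
    tot <- s2a + s2b + s2c
    list(sigma2 = c(among_groups = s2a, among_pops_within = s2b, within = s2c),
         SSD = SSD, df = df,
         phi = c(phi_CT = s2a / tot, phi_SC = s2b / (s2b + s2c),
                 phi_ST = (s2a + s2b) / tot))
  }
}

#' Hierarchical analysis of molecular variance
#'
#' Two- or three-level AMOVA on allele mismatch distances, summed over loci,
#' with permutation tests. Permutation schemes: `phi_ST` permutes individuals
#' among populations (ignoring groups), `phi_SC` permutes individuals among
#' populations within their group, `phi_CT` permutes whole populations among
#' groups. Negative variance components are reported as computed (flagged),
#' not truncated. p-values are `(#{perm >= obs} + 1) / (n_perm + 1)`.
#'
#' @param m a [snp_matrix()].
#' @param pmap a [pop_map()].
#' @param levels 2 (populations only) or 3 (groups / populations / within).
#' @param n_perm permutations per Phi statistic (0 skips testing).
#' @return An `rg_amova` list: `sigma2`, `SSD`, `df`, `phi`, `p_value`,
#'   `flags`.
#' @export
amova <- function(m, pmap, levels = 3, n_perm = 10000) {
  stopifnot(levels %in% c(2, 3))
  g <- m$genotypes
  pop <- match_pops(m, pmap)
  if (nlevels(pop) < 2) {
    # degenerate design: no among-population level; report zeros, flagged
    return(structure(list(
      sigma2 = c(among_pops = 0, within = NA_real_),
      SSD = NULL, df = NULL,
      phi = c(phi_ST = 0),
      p_value = c(phi_ST = NA_real_),
      flags = "single population; Phi undefined, reported as 0",
      levels = 2, n_perm = 0), class = "rg_amova"))
  }
  grp <- if (levels == 3) match_pops(m, pmap, "group") else NULL
  if (levels == 3 && nlevels(grp) < 2)
    stop("three-level AMOVA needs at least two groups")
  obs <- amova_components(g, pop, grp)
  flags <- character(0)
  if (any(obs$sigma2 < 0, na.rm = TRUE))
    flags <- c(flags, "negative variance component retained")
  if (!all(is.finite(obs$phi))) {
    obs$phi[!is.finite(obs$phi)] <- 0
    flags <- c(flags, "undefined Phi reported as 0")
  }
  pval <- rep(NA_real_, length(obs$phi))
  names(pval) <- names(obs$phi)
  if (n_perm > 0) {
    exceed <- setNames(numeric(length(obs$phi)), names(obs$phi))
    pops_by_grp <- if (levels == 3)
      tapply(as.character(pop), as.character(grp), unique)
    for (b in seq_len(n_perm)) {
      # phi_ST: individuals among populations
      p1 <- sample(pop)
      ph <- amova_components(g, p1, if (levels == 3) grp else NULL)$phi
      exceed["phi_ST"] <- exceed["phi_ST"] +
        (ph["phi_ST"] >= obs$phi["phi_ST"])
      if (levels == 3) {
        # phi_SC: individuals among populations within groups
        p2 <- as.character(pop)
        for (gg in levels(grp)) {
          i <- which(grp == gg)
          p2[i] <- p2[i][sample(length(i))]
        }
        p2 <- factor(p2, levels = levels(pop))
        ph2 <- amova_components(g, p2, grp)$phi
        exceed["phi_SC"] <- exceed["phi_SC"] +
          (ph2["phi_SC"] >= obs$phi["phi_SC"])
        # phi_CT: whole populations among groups
        sizes <- vapply(pops_by_grp, length, integer(1))
        newg <- setNames(sample(rep(names(sizes), sizes)), unlist(pops_by_grp))
        g3 <- factor(newg[as.character(pop)], levels = levels(grp))
        ph3 <- amova_components(g, pop, g3)$phi
        exceed["phi_CT"] <- exceed["phi_CT"] +
          (ph3["phi_CT"] >= obs$phi["phi_CT"])
      }
    }
    pval <- (exceed + 1) / (n_perm + 1)
    pval[setdiff(names(pval), c("phi_ST", "phi_SC", "phi_CT"))] <- NA
  }
  structure(list(sigma2 = obs$sigma2, SSD = obs$SSD, df = obs$df,
                 phi = obs$phi, p_value = pval, flags = flags,
                 levels = levels, n_perm = n_perm),
            class = "rg_amova")
}

#' @export
print.rg_amova <- function(x, ...) {
  cat(sprintf("AMOVA (%d-level, SSDs and df summed over loci)\n", x$levels))
  if (!is.null(x$SSD)) print(data.frame(SSD = x$SSD, df = x$df))
  tot <- sum(x$sigma2)
  cat("\nvariance components (% of total):\n")
  for (nm in names(x$sigma2))
    cat(sprintf("  %-20s %10.5f  (%5.1f%%)\n", nm, x$sigma2[nm],
                100 * x$sigma2[nm] / tot))
  cat("\nPhi statistics:\n")
  for (nm in names(x$phi))
    cat(sprintf("  %-8s %7.4f   p = %s\n", nm, x$phi[nm],
                format(x$p_value[nm])))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pairwise PhiST matrix
#'
#' Two-level AMOVA restricted to each population pair, SSDs summed over
#' loci. Negative estimates are reported as computed.
#'
#' @param m a [snp_matrix()].
#' @param pmap a [pop_map()].
#' @return Symmetric population x population matrix of PhiST values.
#' @export
pairwise_phist <- function(m, pmap) {
  pop <- match_pops(m, pmap)
  if (nlevels(pop) < 2) stop("need at least two populations")
  pops <- levels(pop)
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- pop %in% pops[c(i, j)]
    gs <- m$genotypes[sel, , drop = FALSE]
    shared <- colSums(!is.na(gs[pop[sel] == pops[i], , drop = FALSE])) > 0 &
      colSums(!is.na(gs[pop[sel] == pops[j], , drop = FALSE])) > 0
    if (!any(shared)) stop("populations ", pops[i], " and ", pops[j],
                           " share no genotyped loci")
    cm <- amova_components(gs[, shared, drop = FALSE], droplevels(pop[sel]))
    out[i, j] <- out[j, i] <- unname(cm$phi["phi_ST"])
  }
  out
}

#' Diversity-geography regression
#'
#' Simple linear regression of a per-population diversity value on latitude
#' or longitude; returns the Pearson correlation and its two-sided p-value.
#'
#' @param values named numeric vector (names = populations).
#' @param coords data frame with population, lat, lon (see [pop_coords]
#'   behaviour of [pop_map()]).
#' @param axis `"lat"` or `"lon"`.
#' @return List with `r`, `p`, `slope`, and a `degenerate` flag when the
#'   response is constant.
#' @export
diversity_gradient <- function(values, coords, axis = c("lat", "lon")) {
  axis <- match.arg(axis)
  if (length(values) < 3) stop("need at least three populations")
  x <- coords[[axis]][match(names(values), coords$population)]
  if (anyNA(x)) stop("populations missing from coordinates")
  if (sd(x) == 0) stop("zero variance in predictor")
  if (sd(values) == 0)
    return(list(r = 0, p = NA_real_, slope = 0, degenerate = TRUE))
  ct <- cor.test(x, values)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(lm(values ~ x))[2]), degenerate = FALSE)
}
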