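# Environment association: population allele frequencies regressed on
# bioclimatic predictors; a locus is "adaptive" when the joint model fits
# well (adjusted R^2 above threshold) and at least one predictor coefficient
# is individually significant.

#' Population allele frequencies
#'
#' Frequency of the alternate allele over non-missing genes per population.
#'
#' @param m a [snp_matrix()].
#' @param pmap a [pop_map()].
#' @return Populations x loci numeric matrix (NA where a population has no
#'   calls at a locus).
#' @export
population_allele_freqs <- function(m, pmap) {
  cnt <- pop_allele_counts(m, pmap)
  ifelse(cnt$n > 0, cnt$d / cnt$n, NA_real_)
}

#' Multiple-regression adaptive-locus scan
#'
#' Ordinary least squares of each locus's population allele frequencies on
#' all predictors jointly. A locus is flagged adaptive when
#' `R^2_adj > r2_threshold` and at least one coefficient t-test has
#' `p < alpha`. Loci with constant frequencies are skipped and flagged
#' degenerate. No multiple-testing correction is applied across loci by
#' default (set `adjust` to a [p.adjust()] method to change that).
#'
#' @param freqs populations x loci matrix from [population_allele_freqs()].
#' @param predictors data frame of site predictors, rows aligned with
#'   `rownames(freqs)` (or carrying matching row names).
#' @param r2_threshold adjusted-R^2 cutoff.
#' @param alpha per-coefficient significance level.
#' @param adjust optional [p.adjust()] method applied per locus across its
#'   coefficient p-values before flagging; `"none"` (default) mirrors a
#'   per-locus rule.
#' @return An `rg_adaptive` data frame: locus, r2_adj, significant
#'   variables, adaptive and degenerate flags; per-variable p-values as
#'   `attr(, "p_values")`.
#' @export
mlr_adaptive_scan <- function(freqs, predictors, r2_threshold = 0.5,
                              alpha = 0.05, adjust = "none") {
  predictors <- as.data.frame(predictors)
  if (!is.null(rownames(freqs)) && !is.null(rownames(predictors)) &&
      !all(rownames(predictors) == seq_len(nrow(predictors))) &&
      all(rownames(freqs) %in% rownames(predictors)))
    predictors <- predictors[rownames(freqs), , drop = FALSE]
  if (nrow(predictors) != nrow(freqs))
    stop("predictor rows must match populations")
  n <- nrow(freqs); np <- ncol(predictors)
  if (n <= np + 1)
    stop("need more populations than predictors + 1 (n = ", n,
         ", predictors = ", np, ")")
  X <- as.matrix(predictors)
  loci <- colnames(freqs)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(freqs)))
  pmat <- matrix(NA_real_, ncol(freqs), np,
                 dimnames = list(loci, colnames(predictors)))
  r2 <- rep(NA_real_, ncol(freqs))
  degenerate <- logical(ncol(freqs))
  for (j in seq_len(ncol(freqs))) {
    y <- freqs[, j]
    okr <- !is.na(y)
    if (sum(okr) <= np + 1 || sd(y[okr]) == 0) {
      degenerate[j] <- TRUE
      next
    }
    fit <- lm(y ~ ., data = data.frame(y = y[okr], X[okr, , drop = FALSE]))
    sm <- summary(fit)
    r2[j] <- sm$adj.r.squared
    cf <- sm$coefficients
    rows <- setdiff(rownames(cf), "(Intercept)")
    pv <- setNames(cf[rows, "Pr(>|t|)"], rows)
    pmat[j, names(pv)] <- p.adjust(pv, adjust)
  }
  anysig <- apply(pmat, 1, function(p) any(p < alpha, na.rm = TRUE))
  sig <- apply(pmat, 1, function(p) {
    nm <- colnames(pmat)[which(p < alpha)]
    paste(nm, collapse = ",")
  })
  out <- data.frame(locus = loci, r2_adj = r2,
                    significant = sig,
                    adaptive = !degenerate & !is.na(r2) &
                      r2 > r2_threshold & anysig,
                    degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "p_values") <- pmat
  class(out) <- c("rg_adaptive", "data.frame")
  out
}
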