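# Gradient-forest allelic turnover: one regression forest per locus
# (population allele frequency on climate predictors), split improvements
# accumulated along each gradient into monotone cumulative-importance
# curves, and climate grids transformed into genomic-composition space to
# map vulnerability as the current-vs-future Euclidean distance.

#' Tree-depth limit used by gradient forests
#'
#' `floor(log2(0.368 n) / 2)` with a floor of 1, `n` = number of sites.
#'
#' @param n number of training sites.
#' @return Integer depth limit.
#' @export
gf_max_level <- function(n) max(1L, floor(log2(0.368 * n) / 2))

# split improvements of one randomForest tree, measured as the decrease in
# sum-of-squares when the training data are passed down the tree
tree_improvements <- function(tr, X, y) {
  n <- nrow(X)
  node_rows <- vector("list", nrow(tr))
  node_rows[[1]] <- seq_len(n)
  out <- list()
  for (k in seq_len(nrow(tr))) {
    if (tr[k, "status"] != -3) next           # -3 marks a split node
    rows <- node_rows[[k]]
    if (is.null(rows) || length(rows) < 2) next
    v <- tr[k, "split var"]
    sp <- tr[k, "split point"]
    left <- rows[X[rows, v] <= sp]
    right <- setdiff(rows, left)
    node_rows[[tr[k, "left daughter"]]] <- left
    node_rows[[tr[k, "right daughter"]]] <- right
    ssd <- function(r) if (length(r) < 2) 0 else sum((y[r] - mean(y[r]))^2)
    imp <- ssd(rows) - ssd(left) - ssd(right)
    if (imp > 0)
      out[[length(out) + 1]] <- c(var = v, split = sp, imp = imp)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Fit a gradient-forest turnover model
#'
#' Fits one regression forest per locus (allele frequency on the predictors)
#' with the depth limit of [gf_max_level()]. For every split, the decrease
#' in sum-of-squares is recorded against the split position; per locus these
#' improvements are scaled so that they sum to the locus's out-of-bag R^2
#' (negatives truncated to 0), then pooled across loci per predictor,
#' density-standardized over a regular grid of `n_bins` points, and
#' accumulated into the non-decreasing cumulative importance F_p. The total
#' rise of F_p is the predictor's overall importance. Predictors correlated
#' above `cor_threshold` are recorded as groups (used for joint permutation
#' by [gf_permutation_importance()]).
#'
#' @param freqs populations x loci allele-frequency matrix.
#' @param predictors data frame of site predictors (rows = populations).
#' @param n_trees regression trees per locus.
#' @param cor_threshold absolute-correlation threshold for grouping.
#' @param n_bins grid points per cumulative-importance curve.
#' @param keep_forests keep the fitted forests (needed for permutation
#'   importance).
#' @return An `rg_gf` object: `importance`, `cum_importance` (list of
#'   data frames x/F per predictor), `r2` per locus, `cor_groups`,
#'   `config`.
#' @export
fit_gf <- function(freqs, predictors, n_trees = 500, cor_threshold = 0.5,
                   n_bins = 101, keep_forests = FALSE) {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != nrow(freqs))
    stop("predictor rows must match populations")
  if (nrow(freqs) < 6) stop("need at least 6 populations")
  if (any(!is.finite(as.matrix(predictors)))) stop("non-finite predictors")
  keep <- vapply(predictors, function(v) sd(v) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping constant predictors: ",
            paste(names(predictors)[!keep], collapse = ", "))
    predictors <- predictors[, keep, drop = FALSE]
  }
  X <- as.matrix(predictors)
  vars <- colnames(X)
  npop <- nrow(X)
  maxnodes <- 2^gf_max_level(npop)
  loci <- colnames(freqs)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(freqs)))

  splits <- setNames(vector("list", length(vars)), vars)
  r2 <- setNames(rep(NA_real_, ncol(freqs)), loci)
  forests <- if (keep_forests) vector("list", ncol(freqs))
  for (j in seq_len(ncol(freqs))) {
    y <- freqs[, j]
    ok <- !is.na(y)
    if (sum(ok) < 6 || sd(y[ok]) == 0) { r2[j] <- 0; next }
    rf <- randomForest::randomForest(X[ok, , drop = FALSE], y[ok],
                                     ntree = n_trees, maxnodes = maxnodes)
    r2[j] <- max(0, rf$rsq[n_trees])
    if (keep_forests) forests[[j]] <- rf
    if (r2[j] <= 0) next
    # per-tree split improvements, locus-normalized to sum to r2
    acc <- list()
    for (k in seq_len(n_trees)) {
      # degenerate bootstrap samples can yield empty trees; skip them
      tr <- tryCatch(randomForest::getTree(rf, k), error = function(e) NULL)
      if (is.null(tr)) next
      im <- tree_improvements(tr, X[ok, , drop = FALSE], y[ok])
      if (!is.null(im)) acc[[length(acc) + 1]] <- im
    }
    if (!length(acc)) next
    im <- do.call(rbind, acc)
    scale <- r2[j] / sum(im[, "imp"])
    for (v in unique(im[, "var"])) {
      rows <- im[im[, "var"] == v, , drop = FALSE]
      splits[[vars[v]]] <- rbind(splits[[vars[v]]],
                                 cbind(rows[, "split"],
                                       rows[, "imp"] * scale))
    }
  }

  ranges <- lapply(vars, function(v) range(X[, v]))
  names(ranges) <- vars
  cum <- list()
  importance <- setNames(numeric(length(vars)), vars)
  for (v in vars) {
    grid <- seq(ranges[[v]][1], ranges[[v]][2], length.out = n_bins)
    F <- numeric(n_bins)
    sp <- splits[[v]]
    if (!is.null(sp) && nrow(sp)) {
      tot <- sum(sp[, 2])
      bin <- pmin(pmax(findInterval(sp[, 1], grid, rightmost.closed = TRUE),
                       1), n_bins - 1)
      raw <- vapply(seq_len(n_bins - 1), function(b) sum(sp[bin == b, 2]),
                    numeric(1))
      # density standardization: divide by the data density per bin, then
      # rescale so the total rise equals the summed importance
      dens <- vapply(seq_len(n_bins - 1), function(b)
        sum(X[, v] >= grid[b] & X[, v] <= grid[b + 1]), numeric(1))
      stdz <- raw / pmax(dens, 1)
      if (sum(stdz) > 0) stdz <- stdz * tot / sum(stdz)
      F <- c(0, cumsum(stdz))
      importance[v] <- tot
    }
    cum[[v]] <- data.frame(x = grid, F = F)
  }
  # correlation grouping for conditional permutation
  groups <- as.list(vars)
  if (length(vars) > 1) {
    cm <- abs(cor(X))
    adj <- cm > cor_threshold
    comp <- seq_along(vars)
    for (i in seq_along(vars)) for (j in seq_along(vars))
      if (adj[i, j]) comp[comp == comp[j]] <- comp[i]
    groups <- split(vars, comp)
  }
  structure(list(importance = importance, cum_importance = cum,
                 r2 = r2, ranges = ranges, cor_groups = unname(groups),
                 forests = if (keep_forests) forests,
                 predictors = predictors,
                 freqs = if (keep_forests) freqs,
                 config = list(n_trees = n_trees,
                               max_level = gf_max_level(npop),
                               cor_threshold = cor_threshold,
                               n_bins = n_bins,
                               binning = "equal-width grid, density-standardized, rescaled to total importance")),
            class = "rg_gf")
}

#' @export
print.rg_gf <- function(x, ...) {
  cat(sprintf("gradient forest: %d loci (%d with positive fit), %d predictors\n",
              length(x$r2), sum(x$r2 > 0), length(x$importance)))
  cat("overall importance:\n")
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}

#' Joint-permutation predictor importance
#'
#' Permutes each correlation group of predictors jointly (same row
#' permutation for all members) and reports the R^2-weighted mean increase
#' in mean-squared error across loci. Requires `fit_gf(..., keep_forests =
#' TRUE)`.
#'
#' @param model an `rg_gf` fitted with `keep_forests = TRUE`.
#' @param n_perm permutations per group.
#' @return Named numeric vector, one value per correlation group (names are
#'   comma-joined members).
#' @export
gf_permutation_importance <- function(model, n_perm = 25) {
  if (is.null(model$forests)) stop("refit with keep_forests = TRUE")
  X <- as.matrix(model$predictors)
  out <- setNames(numeric(length(model$cor_groups)),
                  vapply(model$cor_groups, paste, "", collapse = ","))
  w <- pmax(model$r2, 0)
  for (gi in seq_along(model$cor_groups)) {
    g <- model$cor_groups[[gi]]
    dmse <- 0; wtot <- 0
    for (j in seq_along(model$forests)) {
      rf <- model$forests[[j]]
      if (is.null(rf) || w[j] <= 0) next
      y <- model$freqs[, j]
      ok <- !is.na(y)
      base <- mean((predict(rf, X[ok, , drop = FALSE]) - y[ok])^2)
      inc <- mean(vapply(seq_len(n_perm), function(b) {
        Xp <- X[ok, , drop = FALSE]
        Xp[, g] <- Xp[sample.int(nrow(Xp)), g, drop = FALSE]
        mean((predict(rf, Xp) - y[ok])^2) - base
      }, numeric(1)))
      dmse <- dmse + w[j] * inc
      wtot <- wtot + w[j]
    }
    out[gi] <- if (wtot > 0) dmse / wtot else 0
  }
  out
}

# evaluate F_p at arbitrary x (clamped to the training range)
gf_curve_at <- function(model, v, x) {
  cv <- model$cum_importance[[v]]
  approx(cv$x, cv$F, xout = pmin(pmax(x, cv$x[1]), cv$x[nrow(cv)]),
         rule = 2)$y
}

#' Transform climate into genomic-composition space
#'
#' Applies each predictor's cumulative-importance curve to the grid (or to a
#' data frame of site values). Cells outside the training gradient are
#' clamped to the curve endpoints and flagged.
#'
#' @param model an `rg_gf`.
#' @param grid a [climate_grid()] or a data frame of predictor values.
#' @return Matrix cells x predictors of F_p values, with `attr(, "clamped")`
#'   (logical per cell) and, for grids, `attr(, "index")` into the grid.
#' @export
transform_climate <- function(model, grid) {
  vars <- intersect(names(model$importance),
                    if (inherits(grid, "climate_grid")) grid_vars(grid)
                    else colnames(grid))
  if (!length(vars)) stop("no shared predictors between model and grid")
  cells <- if (inherits(grid, "climate_grid")) grid_cells(grid)
  else as.matrix(grid)
  out <- vapply(vars, function(v) gf_curve_at(model, v, cells[, v]),
                numeric(nrow(cells)))
  out <- matrix(out, nrow = nrow(cells), dimnames = list(NULL, vars))
  cl <- vapply(vars, function(v)
    cells[, v] < model$ranges[[v]][1] | cells[, v] > model$ranges[[v]][2],
    logical(nrow(cells)))
  clamped <- rowSums(matrix(cl, nrow = nrow(cells))) > 0
  attr(out, "clamped") <- clamped
  attr(out, "index") <- attr(cells, "index")
  out
}

#' Genomic vulnerability map
#'
#' Per-cell Euclidean distance between the gradient-forest compositions of
#' two epochs of the same grid geometry. Masked cells stay masked.
#'
#' @param model an `rg_gf`.
#' @param grid_now,grid_future [climate_grid()]s with identical geometry.
#' @return A [climate_grid()] with single variable `vulnerability`.
#' @export
genomic_vulnerability <- function(model, grid_now, grid_future) {
  if (!inherits(grid_now, "climate_grid") ||
      !inherits(grid_future, "climate_grid"))
    stop("grids must be climate_grid objects")
  if (!same_geometry(grid_now, grid_future)) stop("grid geometry mismatch")
  cn <- transform_climate(model, grid_now)
  cf <- transform_climate(model, grid_future)
  d <- sqrt(rowSums((cn - cf)^2))
  m <- matrix(NA_real_, length(grid_now$y), length(grid_now$x))
  m[attr(cn, "index")] <- d
  climate_grid(grid_now$x, grid_now$y, list(vulnerability = m),
               epoch = "future", mask = grid_now$mask)
}
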