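# Reference-table ABC: summary statistics, scenario choice with
# cross-validation, and local-linear parameter estimation with a logit
# transform to the prior support.
#
# Summary registry (per group structure): for every group the proportion of
# monomorphic loci and the mean and variance of unbiased gene diversity; for
# every group pair the multi-locus Hudson FST (ratio of averages), Nei's
# standard distance, and the proportion of loci monomorphic in the pooled
# pair. The registry is fixed-order, recorded in the reference table's
# metadata, and identical for observed and simulated data.

group_counts <- function(m, pmap) {
  grp <- match_pops(m, pmap, "group")
  cnt <- count_by(m$genotypes, grp)
  list(d = cnt$d, n = cnt$n, groups = rownames(cnt$d))
}

#' Summary-statistic vector for ABC
#'
#' @param m a [snp_matrix()].
#' @param pmap a [pop_map()]; groups define the summary structure.
#' @return Named numeric vector (fixed order for a given set of groups).
#' @export
summarize_snps <- function(m, pmap) {
  gc <- group_counts(m, pmap)
  d <- gc$d; n <- gc$n
  if (any(rowSums(n) < 2)) stop("group with fewer than 2 genes")
  groups <- gc$groups
  out <- numeric(0)
  p <- d / n
  for (g in groups) {
    ok <- n[g, ] >= 2
    mono <- d[g, ] == 0 | d[g, ] == n[g, ]
    h <- ifelse(ok, 2 * p[g, ] * (1 - p[g, ]) * n[g, ] / pmax(n[g, ] - 1, 1), 0)
    out <- c(out, setNames(c(mean(mono), mean(h), var(h)),
                           paste0(c("mono_", "hdiv_", "vdiv_"), g)))
  }
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      a <- groups[i]; b <- groups[j]
      pa <- p[a, ]; pb <- p[b, ]; na <- n[a, ]; nb <- n[b, ]
      # Hudson FST, ratio of averages
      num <- (pa - pb)^2 - pa * (1 - pa) / pmax(na - 1, 1) -
        pb * (1 - pb) / pmax(nb - 1, 1)
      den <- pa * (1 - pb) + pb * (1 - pa)
      fst <- if (sum(den) > 0) sum(num) / sum(den) else 0
      # Nei standard distance over loci
      jx <- mean(pa^2 + (1 - pa)^2)
      jy <- mean(pb^2 + (1 - pb)^2)
      jxy <- mean(pa * pb + (1 - pa) * (1 - pb))
      nei <- -log(jxy / sqrt(jx * jy))
      dp <- d[a, ] + d[b, ]; np <- na + nb
      monop <- mean(dp == 0 | dp == np)
      out <- c(out, setNames(c(fst, nei, monop),
                             paste0(c("fst_", "nei_", "monop_"), a, "_", b)))
    }
  }
  out
}

#' Build an ABC reference table
#'
#' For each scenario, draws parameters from the priors, simulates a SNP
#' matrix, and records its summary vector. Reproducible under a fixed RNG
#' seed.
#'
#' @param specs list of [scenario_spec()]s (named).
#' @param n_per_scenario simulations per scenario.
#' @param n_loci SNP loci per simulated dataset.
#' @param progress print a dot every 100 simulations.
#' @return An `rg_reference` object: `scenario` factor, `params` data frame
#'   (union of parameter names, NA where absent), `sumstats` matrix, `specs`.
#' @export
build_reference <- function(specs, n_per_scenario, n_loci, progress = FALSE) {
  stopifnot(n_per_scenario >= 1)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, "", "name")
  allpar <- unique(unlist(lapply(specs, function(s) s$priors$param)))
  rows_scen <- character(0)
  params <- list()
  stats <- list()
  k <- 0
  for (sn in names(specs)) {
    spec <- specs[[sn]]
    pmap <- scenario_popmap(spec)
    for (i in seq_len(n_per_scenario)) {
      draw <- sample_prior(spec)
      m <- simulate_snps(spec, draw, n_loci)
      s <- summarize_snps(m, pmap)
      k <- k + 1
      rows_scen[k] <- sn
      pv <- setNames(rep(NA_real_, length(allpar)), allpar)
      pv[names(draw)] <- draw
      params[[k]] <- pv
      stats[[k]] <- s
      if (progress && k %% 100 == 0) cat(".")
    }
  }
  if (progress) cat("\n")
  sumstats <- do.call(rbind, stats)
  keep <- rowSums(!is.finite(sumstats)) == 0
  structure(list(scenario = factor(rows_scen[keep], levels = names(specs)),
                 params = as.data.frame(do.call(rbind, params))[keep, ,
                                                                drop = FALSE],
                 sumstats = sumstats[keep, , drop = FALSE],
                 specs = specs, n_loci = n_loci,
                 registry = colnames(sumstats)),
            class = "rg_reference")
}

#' @export
print.rg_reference <- function(x, ...) {
  cat(sprintf("ABC reference table: %d rows, %d summaries, %d loci/dataset\n",
              nrow(x$sumstats), ncol(x$sumstats), x$n_loci))
  print(table(x$scenario))
  invisible(x)
}

# standardized distances of reference rows to an observed vector
ref_distances <- function(sumstats, observed, sds = NULL) {
  if (is.null(sds)) sds <- apply(sumstats, 2, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  z <- sweep(sumstats, 2, sds, "/")
  zo <- observed / sds
  sqrt(rowSums(sweep(z, 2, zo)^2))
}

epanechnikov <- function(d, dmax) {
  w <- 1 - (d / dmax)^2
  w[w < 0] <- 0
  w
}

#' Scenario posterior probabilities
#'
#' Retains the `tolerance` fraction of reference rows nearest the observed
#' summaries (Euclidean distance on SD-standardized summaries), then either
#' reports scenario frequencies (`rejection`), fits a weighted multinomial
#' logistic regression of scenario on summaries over the retained rows and
#' evaluates it at the observed vector (`mnlogit`, the default), or fits a
#' single-hidden-layer neural network (`neuralnet`).
#'
#' @param ref an `rg_reference` from [build_reference()].
#' @param observed named summary vector (same registry as `ref`).
#' @param tolerance fraction of rows retained, in (0, 1].
#' @param method `"mnlogit"`, `"rejection"` or `"neuralnet"`.
#' @return An `rg_model_posterior` list with `prob` (named, sums to 1),
#'   `bayes_factors`, `method`, `tolerance`, `n_retained`.
#' @export
model_posterior <- function(ref, observed,
                            tolerance = 0.05,
                            method = c("mnlogit", "rejection", "neuralnet")) {
  method <- match.arg(method)
  stopifnot(tolerance > 0, tolerance <= 1)
  if (nlevels(ref$scenario) < 2) stop("reference needs at least 2 scenarios")
  observed <- observed[ref$registry]
  d <- ref_distances(ref$sumstats, observed)
  k <- ceiling(tolerance * length(d))
  sel <- order(d)[seq_len(k)]
  scen <- ref$scenario[sel]
  prob <- softmax_probs(ref, sel, d[sel], observed, method)
  if (any(tabulate(scen, nlevels(ref$scenario)) == 0) && method == "rejection")
    warning("some scenarios absent from the retained set; probability 0")
  bf <- outer(prob, prob, function(a, b) a / b)
  structure(list(prob = prob, bayes_factors = bf, method = method,
                 tolerance = tolerance, n_retained = k),
            class = "rg_model_posterior")
}

softmax_probs <- function(ref, sel, dsel, observed, method) {
  lev <- levels(ref$scenario)
  scen <- droplevels(ref$scenario[sel])
  if (method == "rejection" || nlevels(scen) == 1) {
    tab <- table(factor(ref$scenario[sel], levels = lev))
    return(setNames(as.numeric(tab) / sum(tab), lev))
  }
  w <- epanechnikov(dsel, max(dsel) * (1 + 1e-12))
  w[w <= 0] <- min(w[w > 0], 1e-8)
  X <- ref$sumstats[sel, , drop = FALSE]
  mu <- colMeans(X); sg <- apply(X, 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  zo <- (observed - mu) / sg
  dat <- data.frame(scen = scen, Z)
  newd <- as.data.frame(as.list(setNames(zo, colnames(Z))))
  if (method == "mnlogit") {
    fit <- nnet::multinom(scen ~ ., data = dat, weights = w, trace = FALSE,
                          maxit = 500, MaxNWts = 5000)
    p <- predict(fit, newdata = newd, type = "probs")
    if (length(fit$lev) == 2) p <- setNames(c(1 - p, p), fit$lev)
  } else {
    y <- nnet::class.ind(scen)
    fit <- nnet::nnet(as.matrix(Z), y, weights = w, size = 5, softmax = TRUE,
                      trace = FALSE, maxit = 500, MaxNWts = 5000, decay = 0.01)
    p <- drop(predict(fit, as.matrix(rbind(zo))))
  }
  out <- setNames(numeric(length(lev)), lev)
  out[names(p)] <- p
  out / sum(out)
}

#' @export
print.rg_model_posterior <- function(x, ...) {
  cat(sprintf("scenario posterior (%s, tolerance %g, %d retained)\n",
              x$method, x$tolerance, x$n_retained))
  print(round(x$prob, 4))
  invisible(x)
}

#' Cross-validation of scenario choice
#'
#' Classifies reference rows as pseudo-observed datasets with themselves held
#' out of the training set; reports the confusion matrix and the mean
#' correct-identification rate.
#'
#' @param ref an `rg_reference`.
#' @param n_pods_per_scenario pseudo-observed rows per scenario.
#' @param tolerance retained fraction per classification.
#' @param method posterior method (see [model_posterior()]).
#' @return An `rg_cv_model` list: `confusion` (true x assigned), `rate`.
#' @export
cv_model_selection <- function(ref, n_pods_per_scenario, tolerance = 0.05,
                               method = c("mnlogit", "rejection",
                                          "neuralnet")) {
  method <- match.arg(method)
  lev <- levels(ref$scenario)
  pods <- unlist(lapply(lev, function(s) {
    rows <- which(ref$scenario == s)
    if (n_pods_per_scenario > length(rows)) stop("n_pods exceeds rows")
    sample(rows, n_pods_per_scenario)
  }))
  sds <- apply(ref$sumstats, 2, sd)
  conf <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (row in pods) {
    obs <- ref$sumstats[row, ]
    d <- ref_distances(ref$sumstats, obs, sds)
    d[row] <- Inf
    k <- ceiling(tolerance * (length(d) - 1))
    sel <- order(d)[seq_len(k)]
    prob <- softmax_probs(ref, sel, d[sel], obs, method)
    pick <- names(prob)[which.max(prob)]
    conf[as.character(ref$scenario[row]), pick] <-
      conf[as.character(ref$scenario[row]), pick] + 1L
  }
  structure(list(confusion = conf, rate = sum(diag(conf)) / sum(conf),
                 tolerance = tolerance, method = method),
            class = "rg_cv_model")
}

#' @export
print.rg_cv_model <- function(x, ...) {
  cat(sprintf("scenario-choice cross-validation (%s, tolerance %g)\n",
              x$method, x$tolerance))
  print(x$confusion)
  cat(sprintf("mean correct-identification rate: %.1f%%\n", 100 * x$rate))
  invisible(x)
}

logit_to_bounds <- function(x, lo, hi) {
  z <- pmin(pmax((x - lo) / (hi - lo), 1e-8), 1 - 1e-8)
  qlogis(z)
}
inv_logit_from_bounds <- function(z, lo, hi) lo + (hi - lo) * plogis(z)

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which.max(cw >= p)], numeric(1))
}

#' ABC parameter estimation
#'
#' Rejection or local-linear-regression posterior for a single scenario's
#' parameters. With `regression = "loclinear"`, parameters are mapped to the
#' real line by a logit transform of their prior support, regressed on the
#' standardized summaries over the retained rows with Epanechnikov weights,
#' adjusted to the observed summary vector (fitted value at the observation
#' plus residuals), back-transformed, and summarized by weighted equal-tailed
#' quantiles. Estimates therefore always respect the prior bounds.
#'
#' @param ref an `rg_reference` restricted to (or built from) one scenario.
#' @param observed named summary vector.
#' @param tolerance retained fraction.
#' @param regression `"loclinear"` or `"none"` (plain rejection).
#' @param transform `"logit"` (default, needs priors) or `"none"`.
#' @param scenario scenario name when `ref` holds several.
#' @return An `rg_posterior` data frame: parameter, median, q2.5, q97.5,
#'   method; the adjusted draws are attached as `attr(, "draws")`.
#' @export
estimate_params <- function(ref, observed, tolerance = 0.01,
                            regression = c("loclinear", "none"),
                            transform = c("logit", "none"),
                            scenario = NULL) {
  regression <- match.arg(regression)
  transform <- match.arg(transform)
  if (is.null(scenario)) {
    if (nlevels(droplevels(ref$scenario)) > 1)
      stop("reference holds several scenarios; pass `scenario`")
    scenario <- as.character(ref$scenario[1])
  }
  rows <- which(ref$scenario == scenario)
  spec <- ref$specs[[scenario]]
  pars <- spec$priors$param
  th <- as.matrix(ref$params[rows, pars, drop = FALSE])
  S <- ref$sumstats[rows, , drop = FALSE]
  observed <- observed[ref$registry]
  d <- ref_distances(S, observed)
  k <- ceiling(tolerance * length(d))
  sel <- order(d)[seq_len(k)]
  w <- epanechnikov(d[sel], max(d[sel]) * (1 + 1e-12))
  w[w <= 0] <- min(w[w > 0], 1e-8)
  lo <- setNames(spec$priors$lo, pars)[colnames(th)]
  hi <- setNames(spec$priors$hi, pars)[colnames(th)]
  tht <- th[sel, , drop = FALSE]
  if (transform == "logit")
    tht <- mapply(function(j) logit_to_bounds(th[sel, j], lo[j], hi[j]),
                  seq_along(lo))
  tht <- matrix(tht, nrow = length(sel), dimnames = list(NULL, colnames(th)))
  method <- regression
  if (regression == "loclinear") {
    sds <- apply(S, 2, sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    X <- sweep(S[sel, , drop = FALSE], 2, observed)
    X <- sweep(X, 2, sds, "/")
    A <- cbind(1, X)
    fit <- tryCatch(lm.wfit(A, tht, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      warning("singular local-linear regression; falling back to rejection")
      method <- "rejection"
    } else {
      cf <- fit$coefficients
      if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1)
      adj <- matrix(rep(cf[1, ], each = length(sel)), ncol = ncol(tht)) +
        as.matrix(fit$residuals)
      colnames(adj) <- colnames(tht)
      tht <- adj
    }
  } else method <- "rejection"
  draws <- tht
  if (transform == "logit")
    draws <- mapply(function(j) inv_logit_from_bounds(tht[, j], lo[j], hi[j]),
                    seq_along(lo))
  draws <- matrix(draws, nrow = nrow(tht), dimnames = dimnames(tht))
  qs <- t(apply(draws, 2, weighted_quantile, w = w,
                probs = c(0.025, 0.5, 0.975)))
  out <- data.frame(parameter = colnames(th), median = qs[, 2],
                    q2.5 = qs[, 1], q97.5 = qs[, 3], method = method,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "draws") <- draws
  attr(out, "weights") <- w
  class(out) <- c("rg_posterior", "data.frame")
  out
}

#' Cross-validation of ABC parameter estimation
#'
#' Reference rows serve as pseudo-observed datasets (held out of their own
#' estimation); the prediction error is `mean((est - true)^2) / var(true)`
#' per parameter, method and tolerance, so uninformative summaries give
#' errors near 1.
#'
#' @param ref single-scenario `rg_reference`.
#' @param n_pods number of pseudo-observed rows.
#' @param tolerances numeric vector of retained fractions.
#' @param methods subset of `c("rejection", "loclinear")`.
#' @return Data frame: parameter, method, tolerance, error.
#' @export
cv_estimation <- function(ref, n_pods, tolerances = c(0.001, 0.005, 0.01),
                          methods = c("rejection", "loclinear")) {
  scenario <- as.character(ref$scenario[1])
  rows <- which(ref$scenario == scenario)
  if (n_pods > length(rows)) stop("n_pods exceeds rows")
  pods <- sample(rows, n_pods)
  pars <- ref$specs[[scenario]]$priors$param
  out <- list()
  for (tol in tolerances) for (meth in methods) {
    est <- matrix(NA_real_, n_pods, length(pars),
                  dimnames = list(NULL, pars))
    for (i in seq_along(pods)) {
      row <- pods[i]
      sub <- ref
      keep <- setdiff(seq_along(sub$scenario), row)
      sub$scenario <- sub$scenario[keep]
      sub$params <- sub$params[keep, , drop = FALSE]
      sub$sumstats <- sub$sumstats[keep, , drop = FALSE]
      pe <- estimate_params(sub, ref$sumstats[row, ], tolerance = tol,
                            regression = if (meth == "loclinear")
                              "loclinear" else "none",
                            scenario = scenario)
      est[i, pe$parameter] <- pe$median
    }
    truth <- as.matrix(ref$params[pods, pars, drop = FALSE])
    err <- colMeans((est - truth)^2) / apply(truth, 2, var)
    out[[length(out) + 1]] <- data.frame(parameter = pars, method = meth,
                                         tolerance = tol, error = unname(err))
  }
  do.call(rbind, out)
}

#' PCA model checking
#'
#' Fits a PCA to the prior-predictive summaries, projects the observed vector
#' and any posterior-predictive summaries, and flags whether the observation
#' lies inside the axis-aligned 1-99% quantile box of each cloud on the
#' first two components.
#'
#' @param ref_prior `rg_reference` (prior-predictive summaries).
#' @param posterior_draws optional matrix of posterior-predictive summaries.
#' @param observed named summary vector.
#' @return List: `prior_coords`, `posterior_coords`, `observed_coords`,
#'   `inside_prior`, `inside_posterior`.
#' @export
model_check_pca <- function(ref_prior, posterior_draws = NULL, observed) {
  S <- ref_prior$sumstats
  keep <- apply(S, 2, sd) > 0
  pc <- prcomp(S[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  proj <- function(x) {
    x <- x[colnames(S)][keep]
    z <- (x - pc$center) / pc$scale
    drop(z %*% pc$rotation[, 1:2])
  }
  prior2 <- pc$x[, 1:2, drop = FALSE]
  obs2 <- proj(observed)
  inside <- function(cloud) {
    all(vapply(1:2, function(k) {
      q <- quantile(cloud[, k], c(0.01, 0.99))
      obs2[k] >= q[1] && obs2[k] <= q[2]
    }, logical(1)))
  }
  post2 <- NULL
  inside_post <- NA
  if (!is.null(posterior_draws)) {
    post2 <- t(apply(posterior_draws, 1, proj))
    inside_post <- inside(post2)
  }
  list(prior_coords = prior2, posterior_coords = post2,
       observed_coords = obs2, inside_prior = inside(prior2),
       inside_posterior = inside_post)
}

#' Convert generations to years
#'
#' @param t_generations time in generations.
#' @param generation_time years per generation (default 10).
#' @return Time in years.
#' @export
generations_to_years <- function(t_generations, generation_time = 10) {
  t_generations * generation_time
}
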