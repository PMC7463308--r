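# Generalized dissimilarity modelling: pairwise dissimilarity regressed on
# I-spline-transformed site differences with non-negative coefficients and
# the 1 - exp(-eta) link. Geographic distance enters as its own predictor
# (spline of the pairwise great-circle distance).

#' Monotone I-spline basis
#'
#' Order-2 I-splines (cumulative degree-2 B-splines) on a knot sequence
#' taken from quantiles of the gradient: with `n_basis = 3` the knots are
#' the minimum, median and maximum. All basis functions are 0 at the
#' gradient minimum, 1 at the maximum, and non-decreasing; values outside
#' the knot range are clamped.
#'
#' @param x evaluation points.
#' @param n_basis number of basis functions (>= 2).
#' @param knots optional knot vector of length `n_basis` (quantiles of `x`
#'   by default).
#' @return Matrix `length(x) x n_basis` with `attr(, "knots")`.
#' @export
ispline_basis <- function(x, n_basis = 3, knots = NULL) {
  stopifnot(n_basis >= 2)
  if (is.null(knots))
    knots <- unname(quantile(x, seq(0, 1, length.out = n_basis), na.rm = TRUE))
  if (length(knots) != n_basis) stop("need ", n_basis, " knots")
  if (any(diff(knots) < 0)) stop("knots must be non-decreasing")
  # degenerate gradient: basis identically 0 keeps the predictor inert
  if (knots[1] >= knots[n_basis]) {
    out <- matrix(0, length(x), n_basis)
    attr(out, "knots") <- knots
    return(out)
  }
  # collapse duplicated interior knots slightly to keep the basis valid
  eps <- (knots[n_basis] - knots[1]) * 1e-9
  for (i in 2:n_basis) if (knots[i] <= knots[i - 1])
    knots[i] <- knots[i - 1] + eps
  xc <- pmin(pmax(x, knots[1]), knots[n_basis])
  full <- c(rep(knots[1], 3), knots[-c(1, n_basis)],
            rep(knots[n_basis], 3))
  B <- splines::splineDesign(full, xc, ord = 3)
  out <- vapply(seq_len(n_basis), function(i)
    rowSums(B[, (i + 1):(n_basis + 1), drop = FALSE]), numeric(length(x)))
  out <- matrix(out, nrow = length(x))
  attr(out, "knots") <- knots
  out
}

haversine_km <- function(coords) {
  # coords: data.frame with lon, lat
  m <- geosphere::distm(as.matrix(coords[, c("lon", "lat")]),
                        fun = geosphere::distHaversine)
  m / 1000
}

# pair design matrix: |I(x_i) - I(x_j)| per climate predictor basis,
# I(dist_ij) for GEO
gdm_design <- function(predictors, coords, n_basis, knots = NULL) {
  preds <- as.data.frame(predictors)
  ns <- nrow(preds)
  pairs <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  cols <- list(); knot_list <- list()
  for (v in names(preds)) {
    kv <- if (!is.null(knots)) knots[[v]] else NULL
    I <- ispline_basis(preds[[v]], n_basis, kv)
    knot_list[[v]] <- attr(I, "knots")
    cols[[v]] <- abs(I[pairs[, 1], , drop = FALSE] -
                       I[pairs[, 2], , drop = FALSE])
  }
  if (!is.null(coords)) {
    dk <- haversine_km(coords)
    dv <- dk[pairs]
    kg <- if (!is.null(knots)) knots[["GEO"]] else NULL
    Ig <- ispline_basis(dv, n_basis, kg)
    knot_list[["GEO"]] <- attr(Ig, "knots")
    cols[["GEO"]] <- Ig
  }
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(lapply(names(cols), function(v)
    paste0(v, "_", seq_len(n_basis))))
  list(X = X, pairs = pairs, knots = knot_list, vars = names(cols))
}

#' Fit a generalized dissimilarity model
#'
#' Models pairwise dissimilarities `d_ij` as `1 - exp(-eta_ij)` with
#' `eta_ij = b0 + sum_p sum_k b_pk |I_pk(x_pi) - I_pk(x_pj)|`, all
#' coefficients non-negative. Fitting minimises squared error on the link
#' scale (`-log(1 - d)`) by non-negative least squares; deviance explained
#' is `100 (1 - RSS/RSS_null)` on that scale. Geographic great-circle
#' distance (km) enters as predictor `GEO` when coordinates are supplied.
#' Negative response entries are clamped to 0; the response must be
#' symmetric with values below 1.
#'
#' @param response symmetric site x site dissimilarity matrix (e.g. pairwise
#'   PhiST).
#' @param predictors data frame of per-site predictor values.
#' @param coords optional data frame with `lon`, `lat` per site (adds GEO).
#' @param n_basis I-spline basis functions per predictor.
#' @param knots optional named list of knot vectors (used internally by the
#'   permutation machinery).
#' @return An `rg_gdm` object: `intercept`, `coefficients`
#'   (basis x predictor matrix), `knots`, `importance` (max spline height =
#'   sum of coefficients per predictor), `deviance_explained`, `fitted`,
#'   `link_response`.
#' @export
fit_gdm <- function(response, predictors, coords = NULL, n_basis = 3,
                    knots = NULL) {
  response <- as.matrix(response)
  if (nrow(response) < 3) stop("need at least 3 sites")
  if (max(abs(response - t(response)), na.rm = TRUE) > 1e-8)
    stop("response must be symmetric")
  preds <- as.data.frame(predictors)
  if (any(!is.finite(as.matrix(preds)))) stop("non-finite predictors")
  des <- gdm_design(preds, coords, n_basis, knots)
  d <- pmin(pmax(response[des$pairs], 0), 1 - 1e-8)
  eta <- -log(1 - d)
  A <- cbind(`(Intercept)` = 1, des$X)
  fit <- pracma::lsqnonneg(A, eta)
  beta <- setNames(fit$x, colnames(A))
  etahat <- drop(A %*% beta)
  rss <- sum((eta - etahat)^2)
  rss0 <- sum((eta - mean(eta))^2)
  devexp <- if (rss0 > 1e-12) 100 * (1 - rss / rss0) else 0
  cf <- matrix(beta[-1], nrow = n_basis,
               dimnames = list(paste0("I", seq_len(n_basis)), des$vars))
  structure(list(intercept = unname(beta[1]), coefficients = cf,
                 knots = des$knots,
                 importance = colSums(cf),
                 deviance_explained = max(devexp, 0),
                 fitted = 1 - exp(-etahat), link_fitted = etahat,
                 link_response = eta, pairs = des$pairs,
                 n_basis = n_basis, vars = des$vars,
                 predictors = preds, coords = coords),
            class = "rg_gdm")
}

#' @export
print.rg_gdm <- function(x, ...) {
  cat(sprintf("GDM: %d predictors, %d I-splines each, deviance explained %.2f%%\n",
              length(x$vars), x$n_basis, x$deviance_explained))
  cat("importance (max spline height):\n")
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}

#' Predicted dissimilarities from a GDM
#'
#' @param object an `rg_gdm`.
#' @param ... unused.
#' @return Symmetric matrix of fitted dissimilarities.
#' @export
predict.rg_gdm <- function(object, ...) {
  ns <- nrow(object$predictors)
  out <- matrix(0, ns, ns)
  out[object$pairs] <- object$fitted
  out + t(out)
}

#' I-spline curves of a fitted GDM
#'
#' Evaluates each predictor's fitted partial response (the coefficient-
#' weighted I-spline sum) on a grid, for turnover plots.
#'
#' @param model an `rg_gdm`.
#' @param n_points grid points per predictor.
#' @return Data frame: predictor, x, y.
#' @export
gdm_splines <- function(model, n_points = 200) {
  out <- list()
  for (v in model$vars) {
    kn <- model$knots[[v]]
    x <- seq(kn[1], kn[length(kn)], length.out = n_points)
    I <- ispline_basis(x, model$n_basis, kn)
    out[[v]] <- data.frame(predictor = v, x = x,
                           y = drop(I %*% model$coefficients[, v]))
  }
  do.call(rbind, out)
}

#' @export
plot.rg_gdm <- function(x, ...) {
  sp <- gdm_splines(x)
  vars <- unique(sp$predictor)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(vars)))
  on.exit(graphics::par(old))
  for (v in vars) {
    s <- sp[sp$predictor == v, ]
    plot(s$x, s$y, type = "l", xlab = v, ylab = "partial turnover",
         main = v, ...)
  }
  invisible(x)
}

# refit with one variable's site values permuted (GEO permutes site
# identities in the distance structure via a coordinate shuffle)
permuted_fit <- function(response, preds, coords, n_basis, var, perm) {
  if (var == "GEO") {
    fit_gdm(response, preds, coords[perm, , drop = FALSE], n_basis)
  } else {
    p2 <- preds
    p2[[var]] <- p2[[var]][perm]
    fit_gdm(response, p2, coords, n_basis)
  }
}

#' Backward elimination with permutation tests
#'
#' Iteratively: fit the model on the current predictor set; for each
#' predictor build a permutation null of the model deviance by shuffling
#' that predictor's site values and refitting; a predictor is significant
#' when the observed deviance exceeds its null in at least `1 - alpha` of
#' permutations (`p = (#{null >= obs} + 1) / (n_perm + 1)`). While any
#' retained predictor is non-significant, the least-important
#' non-significant one is dropped and the loop repeats. Whole-model
#' significance permutes all predictors jointly.
#'
#' @param response symmetric dissimilarity matrix.
#' @param predictors data frame of site predictors.
#' @param coords optional site coordinates (adds GEO as an eliminable
#'   predictor).
#' @param n_perm permutations per test.
#' @param alpha significance level.
#' @param n_basis I-splines per predictor.
#' @return The final `rg_gdm` with extra fields `elimination` (trace data
#'   frame), `var_p` (final per-variable p-values), `model_p`.
#' @export
backward_eliminate <- function(response, predictors, coords = NULL,
                               n_perm = 100, alpha = 0.05, n_basis = 3) {
  preds <- as.data.frame(predictors)
  have_geo <- !is.null(coords)
  ns <- nrow(preds)
  trace <- list()
  repeat {
    vars <- names(preds)
    if (length(vars) == 0 && !have_geo) {
      warning("all predictors eliminated; returning intercept-only model")
      model <- NULL
      break
    }
    model <- fit_gdm(response, preds, if (have_geo) coords else NULL, n_basis)
    dev_obs <- model$deviance_explained
    pv <- setNames(rep(NA_real_, length(model$vars)), model$vars)
    for (v in model$vars) {
      nulldev <- vapply(seq_len(n_perm), function(b) {
        permuted_fit(response, preds, coords, n_basis, v,
                     sample.int(ns))$deviance_explained
      }, numeric(1))
      pv[v] <- (sum(nulldev >= dev_obs) + 1) / (n_perm + 1)
    }
    insig <- names(pv)[pv > alpha]
    trace[[length(trace) + 1]] <-
      data.frame(step = length(trace) + 1,
                 n_vars = length(model$vars),
                 deviance_explained = dev_obs,
                 dropped = if (length(insig)) {
                   cand <- insig[which.min(model$importance[insig])]
                   cand
                 } else NA_character_)
    if (!length(insig)) break
    drop_var <- trace[[length(trace)]]$dropped
    if (drop_var == "GEO") have_geo <- FALSE
    else preds[[drop_var]] <- NULL
    if (ncol(preds) == 0 && !have_geo) {
      warning("all predictors eliminated; returning intercept-only model")
      model <- NULL
      break
    }
  }
  if (is.null(model)) {
    d <- pmin(pmax(as.matrix(response)[upper.tri(response)], 0), 1 - 1e-8)
    eta <- -log(1 - d)
    model <- structure(list(intercept = mean(eta),
                            coefficients = matrix(0, n_basis, 0),
                            knots = list(), importance = numeric(0),
                            deviance_explained = 0,
                            link_response = eta, n_basis = n_basis,
                            vars = character(0),
                            predictors = preds, coords = NULL),
                       class = "rg_gdm")
    pv <- setNames(numeric(0), character(0))
  }
  # whole-model significance: permute all predictors jointly
  dev_obs <- model$deviance_explained
  model_p <- NA_real_
  if (length(model$vars)) {
    nulldev <- vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(ns)
      p2 <- model$predictors[perm, , drop = FALSE]
      rownames(p2) <- NULL
      fit_gdm(response, p2,
              if (!is.null(model$coords))
                model$coords[perm, , drop = FALSE] else NULL,
              n_basis)$deviance_explained
    }, numeric(1))
    model_p <- (sum(nulldev >= dev_obs) + 1) / (n_perm + 1)
  }
  model$elimination <- do.call(rbind, trace)
  model$var_p <- pv
  model$model_p <- model_p
  model
}
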