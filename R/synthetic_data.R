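# Synthetic study generator: a complete study-shaped dataset with known
# truth — coalescent neutral loci under a configurable divergence scenario,
# adaptive loci as logistic allele-frequency clines along climate gradients,
# spatially autocorrelated climate fields with a shifted "future" copy, and
# a missingness mask. Defaults mirror the study shape that motivated the
# package: 35 populations in three regional groups (10 + 14 southwest /
# central-east China-like plus 11 Japan-like; 45/75/51 diploids, 171 total),
# an 8,782-locus scan matrix of which 49 loci are adaptive, and a 1,383-locus
# complete matrix for demographic inference.

default_pop_layout <- function() {
  sw <- data.frame(population = sprintf("SW%02d", 1:10), group = "SW",
                   n = c(5, 5, 5, 5, 5, 4, 4, 4, 4, 4),
                   lat = seq(26, 33, length.out = 10),
                   lon = seq(99, 104, length.out = 10))
  ce <- data.frame(population = sprintf("CE%02d", 1:14), group = "CE",
                   n = c(rep(6, 5), rep(5, 9)),
                   lat = seq(27, 34, length.out = 14),
                   lon = seq(106, 120, length.out = 14))
  jp <- data.frame(population = sprintf("JP%02d", 1:11), group = "JP",
                   n = c(rep(5, 7), rep(4, 4)),
                   lat = seq(31, 37, length.out = 11),
                   lon = seq(131, 140, length.out = 11))
  rbind(sw, ce, jp)
}

# mean/sd/latitude-trend per synthetic bioclim variable (temperature in
# degrees C, precipitation in mm; BIO4 is a seasonality index)
default_climate_spec <- function() {
  data.frame(var = c("BIO4", "BIO6", "BIO7", "BIO11", "BIO14", "BIO15"),
             mean = c(700, -4, 27, 3, 15, 60),
             sd = c(120, 4, 3, 4, 8, 15),
             lat_trend = c(25, -0.8, 0.5, -0.7, -0.5, 0),
             stringsAsFactors = FALSE)
}

#' Study configuration for the synthetic generator
#'
#' @param n_neutral,n_adaptive neutral and adaptive locus counts (defaults
#'   8733 + 49, the scan-matrix shape).
#' @param scenario a [scenario_spec()]; default the "Japan splits first,
#'   central/east buds from southwest" divergence scenario.
#' @param true_params named parameter vector for `scenario`; the default
#'   uses the published posterior medians of that scenario.
#' @param pops population layout data frame (population, group, n, lat,
#'   lon); default mirrors the 35-population study shape.
#' @param clines data frame (locus index assigned later): `var` (climate
#'   variable), `slope`, `intercept` per adaptive locus; default slope 5 on
#'   the four temperature variables, cycled.
#' @param missing_rate per-genotype missingness in the scan matrix.
#' @param grid_nx,grid_ny,extent climate-field geometry
#'   (lon-min, lon-max, lat-min, lat-max).
#' @param smoothness Gaussian smoothing radius of the climate noise, in
#'   cells.
#' @param future_offsets named per-variable additive offsets for the future
#'   epoch (default +1.5 on the temperature variables, -5 on BIO14).
#' @param seed master seed; every draw in [make_study()] derives from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_neutral = 8733, n_adaptive = 49,
                         scenario = NULL, true_params = NULL,
                         pops = default_pop_layout(),
                         clines = NULL, missing_rate = 0.05,
                         grid_nx = 90, grid_ny = 30,
                         extent = c(95, 145, 24, 38),
                         smoothness = 3,
                         future_offsets = c(BIO4 = 30, BIO6 = 1.5,
                                            BIO7 = 0.5, BIO11 = 1.5,
                                            BIO14 = -5, BIO15 = 0),
                         seed = 1L) {
  if (is.null(scenario)) {
    nd <- tapply(pops$n, pops$group, sum)[c("SW", "CE", "JP")]
    scenario <- builtin_scenarios(n_diploid = nd)$divergence$S2
  }
  if (is.null(true_params))
    true_params <- c(NA_anc = 6.92e5, NSW = 3.00e5, NCE = 9.13e5,
                     NJP = 2.84e5, t1 = 6.39e6, t2 = 3.96e6)
  if (is.null(clines) && n_adaptive > 0) {
    vars <- c("BIO4", "BIO6", "BIO7", "BIO11")
    clines <- data.frame(var = rep(vars, length.out = n_adaptive),
                         slope = 5, intercept = 0,
                         stringsAsFactors = FALSE)
  } else if (!is.null(clines) && n_adaptive > 0) {
    clines <- clines[rep(seq_len(nrow(clines)), length.out = n_adaptive), ,
                     drop = FALSE]
    rownames(clines) <- NULL
  }
  structure(list(n_neutral = n_neutral, n_adaptive = n_adaptive,
                 scenario = scenario, true_params = true_params,
                 pops = pops, clines = clines,
                 missing_rate = missing_rate,
                 grid_nx = grid_nx, grid_ny = grid_ny, extent = extent,
                 smoothness = smoothness, future_offsets = future_offsets,
                 climate = default_climate_spec(), seed = as.integer(seed)),
            class = "study_config")
}

gaussian_blur <- function(m, sigma) {
  if (!is.finite(sigma)) return(matrix(mean(m), nrow(m), ncol(m)))
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(x) {
    # kernel smoothing with edge renormalization
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- k[j - i + r + 1]
      out[i] <- sum(x[j] * w) / sum(w)
    }
    out
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Spatially autocorrelated climate fields
#'
#' Each variable is a latitudinal trend plus Gaussian-smoothed white noise,
#' scaled to the variable's nominal spread; site values are extracted at the
#' population coordinates (nearest cell). Infinite smoothness gives a
#' constant field.
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param nx,ny grid cells per axis.
#' @param climate data frame (var, mean, sd, lat_trend) as in
#'   [study_config()].
#' @param smoothness smoothing radius in cells (may be `Inf`).
#' @param coords optional site coordinates (`lon`, `lat`) for extraction.
#' @param with_trend include the latitudinal trend (disable to study pure
#'   autocorrelation).
#' @return List: `grid` ([climate_grid()]), `sites` (data frame or NULL).
#' @export
make_climate_fields <- function(extent, nx = 90, ny = 30,
                                climate = default_climate_spec(),
                                smoothness = 3, coords = NULL,
                                with_trend = TRUE) {
  x <- seq(extent[1], extent[2], length.out = nx)
  y <- seq(extent[3], extent[4], length.out = ny)
  latm <- matrix(rep(y, nx), ny)
  vals <- list()
  for (i in seq_len(nrow(climate))) {
    noise <- gaussian_blur(matrix(rnorm(ny * nx), ny), smoothness)
    nsd <- sd(noise)
    if (nsd > 0) noise <- noise / nsd
    f <- climate$mean[i] + climate$sd[i] * noise
    if (with_trend)
      f <- f + climate$lat_trend[i] * (latm - mean(y))
    vals[[climate$var[i]]] <- f
  }
  grid <- climate_grid(x, y, vals, epoch = "current")
  sites <- if (!is.null(coords)) extract_sites(grid, coords)
  list(grid = grid, sites = sites)
}

#' Generate a complete synthetic study
#'
#' Neutral loci are simulated under the configured coalescent scenario;
#' adaptive loci are drawn per population as binomial genotypes around a
#' logistic cline `plogis(intercept + slope * z)` in the z-scored site value
#' of the target climate variable (deliberately independent of the
#' coalescent, so cline strength is exactly controlled). Missingness is
#' applied at the configured rate. Everything derives from `config$seed`:
#' the same config gives byte-identical output.
#'
#' @param config a [study_config()].
#' @return List: `snps` ([snp_matrix()]), `pmap` ([pop_map()]), `sites`
#'   (per-population predictors), `grid_now`, `grid_future`
#'   ([climate_grid()]s), `truth` (adaptive locus ids, cline table, scenario
#'   name, true parameters, seed).
#' @export
make_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  pops <- config$pops
  pmap <- pop_map(sample = unlist(mapply(function(p, n)
    paste0(p, "_", seq_len(n)), pops$population, pops$n)),
    population = rep(pops$population, pops$n),
    group = rep(pops$group, pops$n),
    lat = rep(pops$lat, pops$n), lon = rep(pops$lon, pops$n))
  cf <- make_climate_fields(config$extent, config$grid_nx, config$grid_ny,
                            config$climate, config$smoothness,
                            coords = data.frame(lon = pops$lon,
                                                lat = pops$lat))
  sites <- cf$sites
  rownames(sites) <- pops$population

  # neutral loci: coalescent under the scenario; group sample sizes follow
  # the layout, then genes are attributed to populations within groups
  nd <- tapply(pops$n, pops$group, sum)
  neutral <- simulate_snps(config$scenario, config$true_params,
                           config$n_neutral,
                           n_diploid = nd[config$scenario$pops])
  # remap simulated samples (grouped) onto the per-population samples
  g <- neutral$genotypes
  ord <- unlist(lapply(config$scenario$pops, function(gr)
    which(pmap$group == gr)))
  gm <- matrix(NA_integer_, nrow(pmap), ncol(g),
               dimnames = list(pmap$sample, paste0("N", seq_len(ncol(g)))))
  gm[ord, ] <- g
  # adaptive loci: logistic clines in z-scored site climate
  if (config$n_adaptive > 0) {
    cl <- config$clines
    za <- matrix(NA_integer_, nrow(pmap), config$n_adaptive)
    for (j in seq_len(config$n_adaptive)) {
      z <- scale(sites[[cl$var[j]]])[, 1]
      pfreq <- plogis(cl$intercept[j] + cl$slope[j] * z)
      pr <- pfreq[match(pmap$population, pops$population)]
      za[, j] <- rbinom(nrow(pmap), 2, pr)
    }
    colnames(za) <- paste0("A", seq_len(config$n_adaptive))
    gm <- cbind(gm, za)
  }
  m <- snp_matrix(gm)
  if (config$missing_rate > 0) m <- mask_missing(m, config$missing_rate)
  grid_future <- make_future(cf$grid, config$future_offsets)
  truth <- list(adaptive_loci = if (config$n_adaptive > 0)
    paste0("A", seq_len(config$n_adaptive)) else character(0),
    clines = config$clines, scenario = config$scenario$name,
    true_params = config$true_params, seed = config$seed)
  list(snps = m, pmap = pmap, sites = sites, grid_now = cf$grid,
       grid_future = grid_future, truth = truth)
}

#' Shift a climate grid into a future epoch
#'
#' Adds per-variable offsets (scalar or full matrix) and tags the result as
#' future; geometry and mask are preserved.
#'
#' @param grid a [climate_grid()].
#' @param offsets named numeric vector (or list of matrices) of additive
#'   shifts; variables not named are unchanged.
#' @return A [climate_grid()] with `epoch = "future"`.
#' @export
make_future <- function(grid, offsets) {
  vals <- grid$values
  for (v in names(offsets)) {
    if (!v %in% names(vals)) next
    vals[[v]] <- vals[[v]] + offsets[[v]]
  }
  climate_grid(grid$x, grid$y, vals, epoch = "future", mask = grid$mask)
}
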