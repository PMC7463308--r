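# Demographic scenario specification and coalescent SNP simulation.
#
# A scenario is declarative: sampled populations with diploid sample sizes
# and current-size parameter names, plus backward-in-time events whose times,
# sizes and admixture rates refer to named parameters with uniform priors.
# Times are in generations, sizes are diploid effective sizes, the coalescent
# is continuous-time with piecewise-constant N. Each locus carries exactly
# one segregating site, placed uniformly on the total branch length of an
# independent gene tree; since every branch subtends a proper subset of the
# pooled sample, loci are polymorphic overall by construction.

#' Define a demographic scenario
#'
#' @param name scenario label.
#' @param pops character vector of sampled population (group) labels.
#' @param n_diploid named integer vector, diploid samples per population.
#' @param sizes named character vector mapping each population to the name of
#'   its current-size parameter.
#' @param events data frame with columns `time` (parameter name or number),
#'   `type` (`"merge"`, `"admix"`, `"resize"`), `a`, `b`, `c` (population
#'   labels; `b` is the merge target or first admixture source, `c` the
#'   second source), and `x` (size parameter for `resize`, admixture-rate
#'   parameter for `admix`). On a merge the target keeps its own size until a
#'   later resize event changes it.
#' @param priors data frame with columns `param`, `lo`, `hi`; all priors are
#'   uniform.
#' @param constraints optional data frame with columns `larger`, `smaller`:
#'   draws are rejected until `larger > smaller` holds for every row.
#' @return A validated `scenario_spec` object.
#' @export
scenario_spec <- function(name, pops, n_diploid, sizes, events, priors,
                          constraints = NULL) {
  stopifnot(is.character(pops), length(pops) >= 1,
            all(pops %in% names(n_diploid)), all(pops %in% names(sizes)))
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  need <- c("time", "type", "a", "b", "c", "x")
  for (nm in setdiff(need, names(events))) events[[nm]] <- NA_character_
  events <- events[, need]
  if (!all(events$type %in% c("merge", "admix", "resize")))
    stop("unknown event type")
  priors <- as.data.frame(priors, stringsAsFactors = FALSE)
  stopifnot(all(c("param", "lo", "hi") %in% names(priors)),
            all(priors$hi >= priors$lo))
  if (!is.null(constraints)) {
    constraints <- as.data.frame(constraints, stringsAsFactors = FALSE)
    stopifnot(all(c("larger", "smaller") %in% names(constraints)))
  }
  spec <- structure(list(name = name, pops = pops,
                         n_diploid = n_diploid[pops],
                         sizes = sizes[pops], events = events,
                         priors = priors, constraints = constraints),
                    class = "scenario_spec")
  validate_scenario(spec)
  spec
}

#' Validate a scenario specification
#'
#' Checks that every referenced parameter has a prior, every referenced
#' population exists, constraints are satisfiable, and the event sequence
#' connects all sampled populations into a single ancestry (merges and
#' admixtures form one connected component).
#'
#' @param spec a [scenario_spec()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_scenario <- function(spec) {
  pn <- spec$priors$param
  refs <- c(spec$sizes,
            spec$events$time[is.na(suppressWarnings(as.numeric(spec$events$time)))],
            spec$events$x[spec$events$type != "merge" &
                            !is.na(spec$events$x) &
                            is.na(suppressWarnings(as.numeric(spec$events$x)))])
  miss <- setdiff(unique(refs), pn)
  if (length(miss)) stop("parameters without priors: ",
                         paste(miss, collapse = ", "))
  evpops <- na.omit(c(spec$events$a, spec$events$b, spec$events$c))
  if (!all(evpops %in% spec$pops))
    stop("event references unknown population")
  if (!is.null(spec$constraints)) {
    bad <- !(spec$constraints$larger %in% pn & spec$constraints$smaller %in% pn)
    if (any(bad)) stop("constraint references unknown parameter")
  }
  # connectivity: merges and admixtures must join all pops
  if (length(spec$pops) > 1) {
    comp <- seq_along(spec$pops)
    names(comp) <- spec$pops
    link <- function(a, b) {
      ca <- comp[a]; cb <- comp[b]
      comp[comp == ca] <<- cb
    }
    for (i in seq_len(nrow(spec$events))) {
      ev <- spec$events[i, ]
      if (ev$type == "merge") link(ev$a, ev$b)
      if (ev$type == "admix") { link(ev$a, ev$b); link(ev$a, ev$c) }
    }
    if (length(unique(comp)) > 1)
      stop("events do not resolve into a single ancestry")
  }
  invisible(TRUE)
}

#' Draw one parameter vector from the scenario priors
#'
#' Uniform draws for every parameter; draws violating the ordering
#' constraints are rejected and redrawn.
#'
#' @param spec a [scenario_spec()].
#' @param max_tries redraw limit before erroring.
#' @return Named numeric vector of parameter values.
#' @export
sample_prior <- function(spec, max_tries = 10000) {
  pr <- spec$priors
  for (i in seq_len(max_tries)) {
    draw <- setNames(runif(nrow(pr), pr$lo, pr$hi), pr$param)
    ok <- TRUE
    if (!is.null(spec$constraints))
      ok <- all(draw[spec$constraints$larger] > draw[spec$constraints$smaller])
    if (ok) return(draw)
  }
  stop("constraints unsatisfiable within prior bounds")
}

# resolve a name-or-number field against a draw
resolve_param <- function(x, draw) {
  v <- suppressWarnings(as.numeric(x))
  ifelse(is.na(v), unname(draw[x]), v)
}

# numeric event matrix for the C++ simulator (0-based pops, sorted by time)
build_event_matrix <- function(spec, draw) {
  ev <- spec$events
  pidx <- function(p) match(p, spec$pops) - 1L
  n <- nrow(ev)
  out <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    tm <- resolve_param(ev$time[i], draw)
    type <- match(ev$type[i], c("merge", "admix", "resize"))
    a <- pidx(ev$a[i])
    b <- if (!is.na(ev$b[i])) pidx(ev$b[i]) else 0
    cc <- if (!is.na(ev$c[i])) pidx(ev$c[i]) else 0
    x <- if (ev$type[i] == "merge") 0 else resolve_param(ev$x[i], draw)
    out[i, ] <- c(tm, type, a, b, cc, x)
  }
  out[order(out[, 1]), , drop = FALSE]
}

#' Simulate a SNP matrix under a scenario
#'
#' One independent coalescent genealogy per locus under the scenario with the
#' given parameter draw; a single mutation is placed uniformly on the total
#' branch length, so every locus is polymorphic in the pooled sample. Genes
#' are paired into diploid genotypes within populations (Hardy-Weinberg;
#' leaves are exchangeable so fixed pairing is equivalent to random pairing).
#' The simulator emits complete matrices; see [mask_missing()] to emulate
#' missingness.
#'
#' @param spec a [scenario_spec()].
#' @param draw named parameter vector (see [sample_prior()]).
#' @param n_loci number of SNP loci.
#' @param n_diploid optional named vector overriding the spec's sample sizes.
#' @return A [snp_matrix()] with samples named `<pop>_<i>`.
#' @export
simulate_snps <- function(spec, draw, n_loci, n_diploid = NULL) {
  stopifnot(n_loci >= 1)
  nd <- if (is.null(n_diploid)) spec$n_diploid else n_diploid[spec$pops]
  if (anyNA(nd) || any(nd < 1)) stop("invalid sample sizes")
  sizes <- unname(draw[spec$sizes])
  if (anyNA(sizes) || any(sizes <= 0)) stop("invalid parameter draw")
  evm <- build_event_matrix(spec, draw)
  g <- rg_sim_snp_genotypes(as.integer(2 * nd), sizes, evm, as.integer(n_loci))
  rownames(g) <- unlist(lapply(spec$pops, function(p)
    paste0(p, "_", seq_len(nd[[p]]))))
  colnames(g) <- paste0("sim", seq_len(n_loci))
  snp_matrix(g)
}

#' Population map matching a simulated scenario
#'
#' Populations double as groups; placeholder coordinates on a unit grid.
#'
#' @param spec a [scenario_spec()].
#' @param n_diploid optional named vector overriding the spec's sample sizes.
#' @return A [pop_map()] aligned with [simulate_snps()] output.
#' @export
scenario_popmap <- function(spec, n_diploid = NULL) {
  nd <- if (is.null(n_diploid)) spec$n_diploid else n_diploid[spec$pops]
  samples <- unlist(lapply(spec$pops, function(p)
    paste0(p, "_", seq_len(nd[[p]]))))
  pops <- rep(spec$pops, unname(nd))
  pop_map(samples, pops, pops,
          lat = as.numeric(factor(pops, levels = spec$pops)),
          lon = as.numeric(factor(pops, levels = spec$pops)))
}

#' Apply random missingness to a SNP matrix
#'
#' Masks genotype calls independently at the given rate, guaranteeing that
#' each locus keeps at least one call.
#'
#' @param m a [snp_matrix()].
#' @param rate per-genotype missingness probability.
#' @return A [snp_matrix()] with `NA` entries.
#' @export
mask_missing <- function(m, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(m)
  g <- m$genotypes
  drop <- matrix(runif(length(g)) < rate, nrow(g))
  # keep at least one call per locus
  allgone <- which(colSums(!drop) == 0)
  if (length(allgone)) drop[cbind(1L, allgone)] <- FALSE
  g[drop] <- NA_integer_
  snp_matrix(g, radlocus_ids = m$radlocus, pos = m$pos)
}

#' Built-in divergence and demographic scenarios
#'
#' Returns the five three-group divergence scenarios (S1 simultaneous split;
#' S2-S4 the three bifurcating orders, with S2 = Japan splitting first and
#' the central/east group budding off from within the southwest lineage; S5
#' admixed origin of the central/east group), and the three single-group
#' demographic scenarios (D1 expansion; D2 expansion then shrinkage; D3
#' expansion, shrinkage, renewed expansion). Divergence priors follow the
#' published uniform bounds with the `t1 > t2` restriction; demographic
#' priors follow the published single-lineage blocks. All bounds are plain
#' data and can be edited before use.
#'
#' @param n_diploid named diploid sample sizes for the divergence scenarios
#'   (defaults to 45/75/51 for SW/CE/JP).
#' @param n_diploid_demo diploid sample size for the one-population
#'   demographic scenarios (default 51).
#' @return List with elements `divergence` (S1..S5) and `demography`
#'   (D1..D3).
#' @export
builtin_scenarios <- function(n_diploid = c(SW = 45, CE = 75, JP = 51),
                              n_diploid_demo = 51) {
  div_priors <- function(params) {
    all <- data.frame(
      param = c("NA_anc", "NSW", "NCE", "NJP", "t1", "t2", "ra"),
      lo = c(10, 10, 10, 10, 100, 100, 0.001),
      hi = c(1e6, 8e5, 1.6e6, 9e5, 5e7, 1e7, 0.999))
    all[all$param %in% params, ]
  }
  sizes <- c(SW = "NSW", CE = "NCE", JP = "NJP")
  ev <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(time = r[[1]], type = r[[2]],
                 a = r[[3]], b = if (length(r) > 3) r[[4]] else NA,
                 c = if (length(r) > 4) r[[5]] else NA,
                 x = if (length(r) > 5) r[[6]] else NA,
                 stringsAsFactors = FALSE)))
  }
  tcon <- data.frame(larger = "t1", smaller = "t2")
  div <- list(
    S1 = scenario_spec("S1", names(sizes), n_diploid, sizes,
      ev(list("t1", "merge", "CE", "SW"),
         list("t1", "merge", "JP", "SW"),
         list("t1", "resize", "SW", NA, NA, "NA_anc")),
      div_priors(c("NA_anc", "NSW", "NCE", "NJP", "t1"))),
    S2 = scenario_spec("S2", names(sizes), n_diploid, sizes,
      ev(list("t2", "merge", "CE", "SW"),
         list("t1", "merge", "JP", "SW"),
         list("t1", "resize", "SW", NA, NA, "NA_anc")),
      div_priors(c("NA_anc", "NSW", "NCE", "NJP", "t1", "t2")), tcon),
    S3 = scenario_spec("S3", names(sizes), n_diploid, sizes,
      ev(list("t2", "merge", "JP", "CE"),
         list("t1", "merge", "CE", "SW"),
         list("t1", "resize", "SW", NA, NA, "NA_anc")),
      div_priors(c("NA_anc", "NSW", "NCE", "NJP", "t1", "t2")), tcon),
    S4 = scenario_spec("S4", names(sizes), n_diploid, sizes,
      ev(list("t2", "merge", "JP", "SW"),
         list("t1", "merge", "CE", "SW"),
         list("t1", "resize", "SW", NA, NA, "NA_anc")),
      div_priors(c("NA_anc", "NSW", "NCE", "NJP", "t1", "t2")), tcon),
    S5 = scenario_spec("S5", names(sizes), n_diploid, sizes,
      ev(list("t2", "admix", "CE", "SW", "JP", "ra"),
         list("t1", "merge", "JP", "SW"),
         list("t1", "resize", "SW", NA, NA, "NA_anc")),
      div_priors(c("NA_anc", "NSW", "NCE", "NJP", "t1", "t2", "ra")), tcon))

  demo_spec <- function(name, priors, events, constraints = NULL)
    scenario_spec(name, "POP", c(POP = n_diploid_demo), c(POP = "N1"),
                  events, priors, constraints)
  demo <- list(
    D1 = demo_spec("D1",
      data.frame(param = c("Na", "N1", "t3"),
                 lo = c(10, 10, 100), hi = c(1e5, 1.2e6, 1e7)),
      data.frame(time = "t3", type = "resize", a = "POP", b = NA, c = NA,
                 x = "Na", stringsAsFactors = FALSE)),
    D2 = demo_spec("D2",
      data.frame(param = c("Na", "N2", "N1", "t3", "tb"),
                 lo = c(10, 10, 10, 100, 100), hi = c(1e5, 2e6, 3e5, 1.6e7, 1e7)),
      data.frame(time = c("tb", "t3"), type = "resize", a = "POP", b = NA,
                 c = NA, x = c("N2", "Na"), stringsAsFactors = FALSE),
      data.frame(larger = "t3", smaller = "tb")),
    D3 = demo_spec("D3",
      data.frame(param = c("Na", "N2", "Nb", "N1", "t3", "tb", "t4"),
                 lo = c(10, 10, 10, 10, 100, 100, 100),
                 hi = c(1e5, 2e6, 3e5, 1.2e6, 1.6e7, 1e7, 5e6)),
      data.frame(time = c("t4", "tb", "t3"), type = "resize", a = "POP",
                 b = NA, c = NA, x = c("Nb", "N2", "Na"),
                 stringsAsFactors = FALSE),
      data.frame(larger = c("t3", "tb"), smaller = c("tb", "t4"))))
  list(divergence = div, demography = demo)
}

#' Read or write a scenario as JSON
#'
#' The JSON mirrors the `scenario_spec` fields, so bounds and events can be
#' edited outside R.
#'
#' @param spec a [scenario_spec()].
#' @param path file path.
#' @return `read_scenario` returns a [scenario_spec()].
#' @export
write_scenario <- function(spec, path) {
  obj <- unclass(spec)
  obj$n_diploid <- as.list(obj$n_diploid)  # keep names in JSON
  obj$sizes <- as.list(obj$sizes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_spec(x$name, x$pops, unlist(x$n_diploid), unlist(x$sizes),
                x$events, x$priors, x$constraints)
}
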