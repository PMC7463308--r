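# End-to-end pipeline: run the enabled stages off one configuration, write
# their outputs under a run directory, and record a manifest (config hash,
# per-stage seeds, output checksums, wall clock).

stage_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + index * 104729) %% .Machine$integer.max)
}

file_checksums <- function(paths) {
  ok <- file.exists(paths)
  out <- rep(NA_character_, length(paths))
  out[ok] <- unname(tools::md5sum(paths[ok]))
  setNames(out, basename(paths))
}

#' Default pipeline configuration
#'
#' Stage toggles plus the knobs each stage needs; scaled down by default so
#' a full run completes in minutes. Pass the result (possibly edited) to
#' [run_pipeline()], or store it as YAML/JSON.
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds derive from it.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(out_dir = "relictgen_run", seed = 1) {
  list(out_dir = out_dir, seed = seed,
       synth = list(enabled = TRUE, n_neutral = 500, n_adaptive = 10,
                    missing_rate = 0.05),
       filter = list(enabled = TRUE, min_pop_frac = 0.6, min_samples = 120,
                     maf = 0.01, one_per_locus = TRUE),
       stats = list(enabled = TRUE, amova_levels = 3, n_perm = 200,
                    min_n = 5),
       abc = list(enabled = FALSE, n_per_scenario = 200, n_loci = 200,
                  tolerance = 0.05),
       outliers = list(enabled = TRUE, method = "fdist", n_sims = 2000,
                       fdr = 0.01, q = 0.001,
                       bayes = list(n_iter = 200, thin = 5, n_pilot = 5,
                                    pilot_len = 100, burnin = 500)),
       adaptive = list(enabled = TRUE, r2_threshold = 0.5, alpha = 0.05),
       gdm = list(enabled = TRUE, n_perm = 50, alpha = 0.05),
       gf = list(enabled = TRUE, n_trees = 100),
       vulnerability = list(enabled = TRUE))
}

#' Run the pipeline
#'
#' Executes the enabled stages in order — synth, filter, stats, abc,
#' outliers, adaptive, gdm, gf, vulnerability — writing stage outputs under
#' `config$out_dir` and a `manifest.json` describing the run. Stages read
#' only their predecessors' in-memory results; nothing mutates an earlier
#' stage's files. Identical config and seed reproduce identical checksums
#' for the deterministic stages.
#'
#' @param config nested list from [pipeline_config()], or a path to a YAML
#'   or JSON file holding one.
#' @return The manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir), !is.null(config$seed))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  stages <- c("synth", "filter", "stats", "abc", "outliers", "adaptive",
              "gdm", "gf", "vulnerability")
  outputs <- character(0)
  for (si in seq_along(stages)) {
    st <- stages[si]
    sc <- config[[st]]
    if (is.null(sc) || !isTRUE(sc$enabled)) next
    seed <- stage_seed(config$seed, si)
    set.seed(seed)
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(run_stage(st, sc, state, config$out_dir),
                      error = function(e)
                        stop("stage '", st, "' failed: ", conditionMessage(e),
                             " (partial outputs kept in ", config$out_dir,
                             ")", call. = FALSE))
    manifest$stages[[st]] <- list(seed = seed,
                                  seconds = round(proc.time()[["elapsed"]] - t0, 2),
                                  outputs = as.list(file_checksums(files)))
    outputs <- c(outputs, files)
  }
  manifest$n_stages <- length(manifest$stages)
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

run_stage <- function(st, sc, state, out_dir) {
  p <- function(...) file.path(out_dir, paste0(...))
  switch(st,
    synth = {
      cfg <- study_config(n_neutral = sc$n_neutral,
                          n_adaptive = sc$n_adaptive,
                          missing_rate = sc$missing_rate,
                          seed = stage_seed(sc$n_neutral, 1))
      study <- make_study(cfg)
      state$study <- study
      state$snps <- study$snps
      write_genotypes(study$snps, p("genotypes.tsv"), "table")
      write.table(as.data.frame(study$pmap), p("popmap.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      write.table(cbind(population = rownames(study$sites), study$sites),
                  p("sites.csv"), sep = ",", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(study$truth[c("adaptive_loci", "scenario",
                                         "true_params", "seed")],
                           p("truth.json"), auto_unbox = TRUE, digits = NA)
      c(p("genotypes.tsv"), p("popmap.csv"), p("sites.csv"), p("truth.json"))
    },
    filter = {
      m <- state$snps
      m <- filter_within_pop_presence(m, state$study$pmap, sc$min_pop_frac)
      m <- filter_sample_coverage(m, sc$min_samples)
      m <- filter_maf(m, sc$maf)
      if (isTRUE(sc$one_per_locus)) m <- one_snp_per_radlocus(m)
      state$snps <- m
      write_genotypes(m, p("filtered.tsv"), "table")
      p("filtered.tsv")
    },
    stats = {
      div <- diversity(state$snps, state$study$pmap, min_n = sc$min_n)
      am <- amova(state$snps, state$study$pmap, levels = sc$amova_levels,
                  n_perm = sc$n_perm)
      phist <- pairwise_phist(state$snps, state$study$pmap)
      state$phist <- phist
      write.table(div, p("diversity.csv"), sep = ",", row.names = FALSE,
                  quote = FALSE)
      amtab <- data.frame(statistic = names(am$phi), value = am$phi,
                          p_value = am$p_value[names(am$phi)])
      write.table(amtab, p("amova.csv"), sep = ",", row.names = FALSE,
                  quote = FALSE)
      write.table(phist, p("phist.csv"), sep = ",", col.names = NA,
                  quote = FALSE)
      c(p("diversity.csv"), p("amova.csv"), p("phist.csv"))
    },
    abc = {
      specs <- builtin_scenarios()$divergence
      ref <- build_reference(specs, sc$n_per_scenario, sc$n_loci)
      obs <- summarize_snps(state$snps, state$study$pmap)
      post <- model_posterior(ref, obs, tolerance = sc$tolerance)
      out <- data.frame(scenario = names(post$prob), prob = post$prob)
      write.table(out, p("abc_model_choice.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      p("abc_model_choice.csv")
    },
    outliers = {
      pm <- state$study$pmap
      res <- NULL
      files <- character(0)
      if (sc$method %in% c("fdist", "both")) {
        fd <- fdist_scan(state$snps, pm, n_sims = sc$n_sims, fdr = sc$fdr)
        write.table(fd, p("outliers_fdist.csv"), sep = ",",
                    row.names = FALSE, quote = FALSE)
        files <- c(files, p("outliers_fdist.csv"))
        res <- fd
      }
      if (sc$method %in% c("bayes", "both")) {
        b <- sc$bayes
        bs <- bayescan_scan(state$snps, pm, n_iter = b$n_iter,
                            thin = b$thin, n_pilot = b$n_pilot,
                            pilot_len = b$pilot_len, burnin = b$burnin,
                            q_threshold = sc$q)
        write.table(bs, p("outliers_bayes.csv"), sep = ",",
                    row.names = FALSE, quote = FALSE)
        files <- c(files, p("outliers_bayes.csv"))
        res <- if (sc$method == "both") {
          both <- intersect_outliers(bs, fd)
          res$flag <- res$locus %in% both
          res
        } else bs
      }
      state$outliers <- res
      files
    },
    adaptive = {
      freqs <- population_allele_freqs(state$snps, state$study$pmap)
      loci <- state$outliers$locus[state$outliers$flag]
      if (!length(loci)) loci <- state$outliers$locus
      scan <- mlr_adaptive_scan(freqs[, colnames(freqs) %in% loci,
                                      drop = FALSE],
                                state$study$sites,
                                r2_threshold = sc$r2_threshold,
                                alpha = sc$alpha)
      state$adaptive <- scan
      write.table(scan, p("adaptive.csv"), sep = ",", row.names = FALSE,
                  quote = FALSE)
      p("adaptive.csv")
    },
    gdm = {
      pm <- state$study$pmap
      pops <- rownames(state$phist)
      pc <- pop_coords(pm)[pops, ]
      model <- backward_eliminate(state$phist,
                                  state$study$sites[pops, , drop = FALSE],
                                  coords = pc[, c("lon", "lat")],
                                  n_perm = sc$n_perm, alpha = sc$alpha)
      out <- data.frame(predictor = model$vars,
                        importance = model$importance,
                        p = model$var_p[model$vars])
      attr_line <- sprintf("# deviance_explained=%.2f model_p=%s",
                           model$deviance_explained, format(model$model_p))
      writeLines(c(attr_line,
                   paste(c("predictor,importance,p"),
                         collapse = ",")), p("gdm.csv"))
      write.table(out, p("gdm.csv"), sep = ",", row.names = FALSE,
                  quote = FALSE, append = TRUE, col.names = FALSE)
      state$gdm <- model
      p("gdm.csv")
    },
    gf = {
      freqs <- population_allele_freqs(state$snps, state$study$pmap)
      model <- fit_gf(freqs, state$study$sites, n_trees = sc$n_trees)
      state$gf <- model
      imp <- data.frame(predictor = names(model$importance),
                        importance = model$importance)
      write.table(imp, p("gf_importance.csv"), sep = ",",
                  row.names = FALSE, quote = FALSE)
      p("gf_importance.csv")
    },
    vulnerability = {
      vul <- genomic_vulnerability(state$gf, state$study$grid_now,
                                   state$study$grid_future)
      write_ascii_grid(vul, "vulnerability", p("vulnerability.asc"))
      p("vulnerability.asc")
    },
    stop("unknown stage ", st))
}
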