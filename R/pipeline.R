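#' Run the full gene-flow analysis pipeline
#'
#' Orchestrates simulate (or load) -> validate -> diversity ->
#' differentiation -> spatial -> fsgs -> mating -> paternity under one
#' config, writing publication-shaped CSV tables, correlogram/O-ring series
#' and a machine-readable run manifest. Every stochastic stage receives a
#' seed derived deterministically from the master seed (master + a fixed
#' per-stage offset: 1 validate/sim, 2 diversity, 3 differentiation,
#' 4 spatial, 5 fsgs, 6 mating, 7 paternity), so one config yields
#' byte-identical outputs on re-runs.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure: `out_dir`; either `simulate = TRUE` plus `sim` (arguments
#'   for [sim_config()]) or `inputs` (paths `genotypes`, `coords`, `arrays`,
#'   `offspring`); `seed` (master seed); `stages` (character subset of
#'   `c("diversity", "differentiation", "spatial", "fsgs", "mating",
#'   "paternity")`, default all); and optional per-stage parameter blocks
#'   `diversity` (hwe, chain sizes), `differentiation` (n_perm), `spatial`
#'   (ring_width, max_r, n_sim), `fsgs` (class_edges, n_perm),
#'   `mating` (n_boot, max_pairs), `paternity` (n_events, n_candidates,
#'   prop_sampled, prop_loci_typed, error_rate), `min_offspring`.
#' @return (invisibly) a list of stage results; files are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage_seed <- function(k) seed + k
  stages <- config$stages
  if (is.null(stages))
    stages <- c("diversity", "differentiation", "spatial", "fsgs",
                "mating", "paternity")
  manifest <- list(package = "orchidflow",
                   version = as.character(utils::packageVersion("orchidflow")),
                   master_seed = seed, stages = stages)
  results <- list()

  # --- inputs -------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim_args <- config$sim
    if (is.null(sim_args)) sim_args <- list()
    sim_args$rng_seed <- stage_seed(1L)
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(scfg, out_dir = file.path(out_dir, "simulated"))
    adults <- sim$adults; coords <- sim$positions
    arrays_map <- sim$arrays; offspring <- sim$offspring
    results$truth <- sim$truth
    manifest$inputs <- list(simulated = TRUE, sim_seed = stage_seed(1L))
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("config must set simulate: true or give inputs")
    adults <- read_genotype_csv(inp$genotypes)
    coords <- read_coords_csv(inp$coords)
    arrays_map <- if (!is.null(inp$arrays)) read_arrays_csv(inp$arrays)
    offspring <- if (!is.null(inp$offspring)) read_genotype_csv(inp$offspring)
    manifest$inputs <- inp
  }
  min_off <- if (is.null(config$min_offspring)) 5L else config$min_offspring
  vrep <- validate_dataset(adults, coords, arrays_map, offspring,
                           min_offspring = min_off)
  results$validation <- vrep
  manifest$counts <- list(n_adults = length(adults$samples),
                          n_offspring = if (!is.null(offspring))
                            length(offspring$samples) else 0L,
                          capsules_retained = vrep$n_retained,
                          capsules_excluded = vrep$n_excluded,
                          offspring_retained = vrep$n_offspring_retained)

  subpops <- unique(coords$subpop[coords$id %in% adults$samples])

  # --- diversity ----------------------------------------------------------
  if ("diversity" %in% stages) {
    dv <- config$diversity
    hwe_params <- list(
      dememorization = dv$dememorization %||% 1000L,
      batches = dv$batches %||% 100L,
      iterations = dv$iterations %||% 1000L,
      seed = stage_seed(2L))
    groups <- c(list(adults = adults$samples),
                if (!is.null(offspring)) list(offspring = NULL))
    tabs <- list(adults = locus_summary(adults, hwe = TRUE,
                                        hwe_params = hwe_params))
    if (!is.null(offspring))
      tabs$offspring <- locus_summary(offspring, hwe = TRUE,
                                      hwe_params = hwe_params)
    t1 <- do.call(rbind, lapply(names(tabs), function(nm)
      cbind(cohort = nm, tabs[[nm]])))
    utils::write.csv(t1, file.path(out_dir, "table1_diversity_cohorts.csv"),
                     row.names = FALSE)
    ad_by_pop <- lapply(stats::setNames(subpops, subpops), function(sp)
      adults$samples[coords$subpop[match(adults$samples, coords$id)] == sp])
    pops <- lapply(ad_by_pop, function(ids) locus_summary(adults, ids))
    t2 <- do.call(rbind, lapply(names(pops), function(nm) {
      mm <- colMeans(pops[[nm]][, c("Na", "Ne", "I", "Ho", "He", "Fis")],
                     na.rm = TRUE)
      data.frame(subpop = nm, n = length(ad_by_pop[[nm]]), t(mm))
    }))
    utils::write.csv(t2, file.path(out_dir, "table2_diversity_subpops.csv"),
                     row.names = FALSE)
    results$diversity <- list(cohorts = tabs, subpops = pops,
                              comparison = if (length(pops) >= 2L)
                                compare_locuswise_stats(pops))
  }

  # --- differentiation ----------------------------------------------------
  if ("differentiation" %in% stages) {
    dn <- config$differentiation
    lab <- coords$subpop[match(adults$samples, coords$id)]
    am <- amova(adults, lab, n_perm = dn$n_perm %||% 999L,
                seed = stage_seed(3L))
    t3 <- am$table
    t3$Fst <- c(am$Fst, NA, NA); t3$p <- c(am$p, NA, NA)
    t3$Gpst <- c(am$Gpst, NA, NA)
    utils::write.csv(t3, file.path(out_dir, "table3_amova.csv"),
                     row.names = FALSE)
    results$differentiation <- am
  }

  # --- spatial point pattern ----------------------------------------------
  if ("spatial" %in% stages) {
    sp <- config$spatial
    ad_coords <- coords[coords$id %in% adults$samples, , drop = FALSE]
    oring <- lapply(stats::setNames(subpops, subpops), function(spp) {
      pts <- ad_coords[ad_coords$subpop == spp, , drop = FALSE]
      o_ring_analysis(pts, ring_width = sp$ring_width %||% 1,
                      max_r = sp$max_r %||% NULL,
                      n_sim = sp$n_sim %||% 999L, seed = stage_seed(4L))
    })
    ser <- do.call(rbind, lapply(names(oring), function(nm)
      data.frame(subpop = nm, r = oring[[nm]]$r, O = oring[[nm]]$O,
                 env_lo = oring[[nm]]$env_lo, env_hi = oring[[nm]]$env_hi,
                 classification = oring[[nm]]$classification)))
    utils::write.csv(ser, file.path(out_dir, "oring_series.csv"),
                     row.names = FALSE)
    results$spatial <- oring
  }

  # --- fine-scale genetic structure ---------------------------------------
  if ("fsgs" %in% stages) {
    fg <- config$fsgs
    edges <- fg$class_edges %||% default_class_edges()
    groups <- c(stats::setNames(as.list(subpops), subpops),
                list(all = NULL))
    fsgs_res <- lapply(groups, function(gsel) {
      ids <- if (is.null(gsel)) NULL else
        adults$samples[coords$subpop[match(adults$samples,
                                           coords$id)] == gsel]
      fsgs_analysis(adults, coords, group = ids, class_edges = edges,
                    n_perm = fg$n_perm %||% 1000L, seed = stage_seed(5L))
    })
    ser <- do.call(rbind, lapply(names(fsgs_res), function(nm) {
      cg <- fsgs_res[[nm]]$correlogram
      data.frame(group = nm, lo = cg$edges[-length(cg$edges)],
                 hi = cg$edges[-1L], d_mean = cg$d_mean,
                 F_mean = cg$F_mean, n_pairs = cg$n_pairs,
                 perm_lo = cg$perm_lo, perm_hi = cg$perm_hi,
                 significant = cg$significant)
    }))
    utils::write.csv(ser, file.path(out_dir, "correlogram_series.csv"),
                     row.names = FALSE)
    sp_tab <- do.call(rbind, lapply(names(fsgs_res), function(nm) {
      sl <- fsgs_res[[nm]]$slope; cu <- fsgs_res[[nm]]$curvature
      data.frame(group = nm, b_LF = sl$b_LF, se_jack = sl$se_jack,
                 Sp = sl$Sp, F1 = sl$F1,
                 k = if (is.null(cu)) NA_real_ else cu$k,
                 verdict = if (is.null(cu)) NA_character_ else cu$verdict)
    }))
    utils::write.csv(sp_tab, file.path(out_dir, "fsgs_sp_curvature.csv"),
                     row.names = FALSE)
    results$fsgs <- fsgs_res
  }

  # --- mating system -------------------------------------------------------
  arr <- NULL
  if (!is.null(arrays_map) && !is.null(offspring) &&
      any(c("mating", "paternity") %in% stages))
    arr <- progeny_arrays(arrays_map, adults, offspring,
                          min_offspring = min_off)
  if ("mating" %in% stages && !is.null(arr)) {
    mt <- config$mating
    fit <- fit_mixed_mating(arr)
    cp <- correlated_paternity(arr, max_pairs = mt$max_pairs %||% Inf,
                               seed = stage_seed(6L))
    bs_mm <- bootstrap_families(arr, "mixed_mating",
                                n_boot = mt$n_boot %||% 1000L,
                                seed = stage_seed(6L))
    bs_cp <- bootstrap_families(arr, "correlated_paternity",
                                n_boot = mt$n_boot %||% 1000L,
                                seed = stage_seed(6L),
                                max_pairs = mt$max_pairs %||% Inf)
    t4 <- fit$families
    utils::write.csv(t4, file.path(out_dir, "table4_mating_system.csv"),
                     row.names = FALSE)
    t5 <- data.frame(
      parameter = c("r_t", "r_pm", "r_ps", "r_ps_minus_r_pm", "N_ep", "F_m"),
      estimate = c(cp$r_t, cp$r_pm, cp$r_ps, cp$r_ps_minus_r_pm, cp$N_ep,
                   fit$F_m),
      se = c(NA, bs_cp$se[c("r_pm", "r_ps", "r_ps_minus_r_pm")], NA, NA))
    utils::write.csv(t5, file.path(out_dir, "table5_correlated_mating.csv"),
                     row.names = FALSE)
    results$mating <- list(fit = fit, correlated = cp,
                           boot_mm = bs_mm, boot_cp = bs_cp)
  }

  # --- paternity -----------------------------------------------------------
  if ("paternity" %in% stages && !is.null(arr)) {
    pt <- config$paternity
    freqs <- allele_frequencies(adults)
    settings <- list(
      n_events = pt$n_events %||% 10000L,
      n_candidates = pt$n_candidates %||% length(adults$samples),
      prop_sampled = pt$prop_sampled %||% 0.5,
      prop_loci_typed = pt$prop_loci_typed %||% 0.9941,
      error_rate = pt$error_rate %||% 0.012)
    thr <- calibrate_confidence(freqs, settings, seed = stage_seed(7L))
    pa <- assign_paternity(arr, thr, freqs = freqs,
                           error_rate = settings$error_rate,
                           coords = coords)
    utils::write.csv(pa$capsules, file.path(out_dir, "table6_paternity.csv"),
                     row.names = FALSE)
    results$paternity <- list(thresholds = thr, assignment = pa,
                              dispersal = dispersal_summary(pa))
    manifest$paternity_settings <- settings
  }

  manifest$seeds <- stats::setNames(as.list(seed + 1:7),
                                    c("simulate", "diversity",
                                      "differentiation", "spatial", "fsgs",
                                      "mating", "paternity"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
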