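#' Simulation configuration for a spatially explicit SSR population
#'
#' Defaults emulate the study system the package targets: three
#' sub-populations of clumped adults on rectangles separated by > 100 m of
#' unsuitable matrix (56, 39 and 60 adults on 140x120, 80x220 and 40x100 m
#' plots), 15 unlinked codominant loci with 2-14 alleles each, near-complete
#' outcrossing, one pollen donor per capsule, long exponential pollen
#' dispersal (scale 300 m) against short exponential seed dispersal (scale
#' 5 m), and progeny-array family sizes 189, 182, 187, 56, 181, 169, 24, 112.
#'
#' @param n_subpops number of sub-populations.
#' @param subpop_rectangles list of `c(x0, y0, width, height)` in metres; the
#'   defaults leave > 100 m gaps between rectangles.
#' @param subpop_labels labels, e.g. `"A"`, `"B"`, `"C"`.
#' @param n_adults adults per sub-population (recycled).
#' @param n_loci number of SSR loci.
#' @param alleles_per_locus inclusive range `c(min, max)` of allele counts.
#' @param allele_freq_concentration Dirichlet concentration for founder
#'   frequencies (1 = uniform simplex; larger = more even frequencies).
#' @param selfing_rate probability an offspring is selfed, in `[0, 1]`.
#' @param pollen_kernel,seed_kernel list `list(family, scale)` with family
#'   `"exponential"` (radial distance ~ Exp(scale)) or `"gaussian"` (isotropic
#'   normal displacement, sd = scale); scale in metres.
#' @param cluster_process list `list(n_parents, mean_offspring, radius)` of the
#'   Thomas-type process used for adult positions (per sub-population).
#' @param n_generations non-overlapping generations of forward simulation.
#' @param capsules list `list(n, sizes, mothers)`; `sizes` recycled to `n`
#'   capsules, `mothers` either `"random"` or explicit adult ids.
#' @param n_donors pollen donors per capsule (1 = single-donor pollinium mode).
#' @param genotyping_error_rate,missing_rate per-allele-slot rates in `[0, 1]`.
#' @param rng_seed integer seed; every simulation entry point resets the RNG
#'   from it so a fixed config yields bit-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subpops = 3L,
                       subpop_rectangles = list(c(0, 0, 140, 120),
                                                c(260, 0, 80, 220),
                                                c(460, 0, 40, 100)),
                       subpop_labels = c("A", "B", "C"),
                       n_adults = c(56L, 39L, 60L),
                       n_loci = 15L,
                       alleles_per_locus = c(2L, 14L),
                       allele_freq_concentration = 1,
                       selfing_rate = 0,
                       pollen_kernel = list(family = "exponential", scale = 300),
                       seed_kernel = list(family = "exponential", scale = 5),
                       cluster_process = list(n_parents = 8L,
                                              mean_offspring = 10,
                                              radius = 5),
                       n_generations = 5L,
                       capsules = list(n = 8L,
                                       sizes = c(189L, 182L, 187L, 56L,
                                                 181L, 169L, 24L, 112L),
                                       mothers = "random"),
                       n_donors = 1L,
                       genotyping_error_rate = 0,
                       missing_rate = 0,
                       rng_seed = 1L) {
  cfg <- list(n_subpops = as.integer(n_subpops),
              subpop_rectangles = subpop_rectangles,
              subpop_labels = subpop_labels,
              n_adults = rep_len(as.integer(n_adults), n_subpops),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              allele_freq_concentration = allele_freq_concentration,
              selfing_rate = selfing_rate,
              pollen_kernel = pollen_kernel,
              seed_kernel = seed_kernel,
              cluster_process = cluster_process,
              n_generations = as.integer(n_generations),
              capsules = capsules,
              n_donors = as.integer(n_donors),
              genotyping_error_rate = genotyping_error_rate,
              missing_rate = missing_rate,
              rng_seed = as.integer(rng_seed))
  stopifnot(length(cfg$subpop_rectangles) == cfg$n_subpops,
            length(cfg$subpop_labels) == cfg$n_subpops)
  if (cfg$selfing_rate < 0 || cfg$selfing_rate > 1)
    stop("selfing_rate must be in [0, 1]")
  for (r in c(cfg$genotyping_error_rate, cfg$missing_rate))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  if (cfg$pollen_kernel$scale <= 0 || cfg$seed_kernel$scale <= 0)
    stop("kernel scales must be > 0")
  if (!cfg$pollen_kernel$family %in% c("exponential", "gaussian") ||
      !cfg$seed_kernel$family %in% c("exponential", "gaussian"))
    stop("kernel family must be 'exponential' or 'gaussian'")
  if (diff(cfg$alleles_per_locus) < 0 || cfg$alleles_per_locus[1L] < 2L)
    stop("alleles_per_locus must be an increasing range with min >= 2")
  class(cfg) <- "sim_config"
  cfg
}

# radial kernel draw: n distances in metres
kernel_rdist <- function(kernel, n) {
  switch(kernel$family,
         exponential = stats::rexp(n, rate = 1 / kernel$scale),
         # isotropic Gaussian displacement => Rayleigh radial distance
         gaussian = kernel$scale * sqrt(stats::rchisq(n, df = 2)),
         stop("unknown kernel family"))
}

# kernel weight at distance d (unnormalized density along distance for
# father sampling)
kernel_weight <- function(kernel, d) {
  switch(kernel$family,
         exponential = exp(-d / kernel$scale),
         gaussian = exp(-d^2 / (2 * kernel$scale^2)),
         stop("unknown kernel family"))
}

#' Simulate clustered adult positions (Thomas-type process)
#'
#' Cluster parents are placed uniformly in each sub-population rectangle,
#' offspring counts are Poisson around each parent with isotropic Gaussian
#' displacement of the configured radius; points falling outside the
#' rectangle are rejected. Exactly `n_adults` points per sub-population are
#' kept. As the cluster radius grows the pattern converges to complete
#' spatial randomness.
#'
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$rng_seed`.
#' @return data frame `id, x, y, subpop, cohort`.
#' @export
simulate_positions <- function(config, seed = config$rng_seed) {
  set.seed(seed)
  cp <- config$cluster_process
  out <- vector("list", config$n_subpops)
  for (s in seq_len(config$n_subpops)) {
    rect <- config$subpop_rectangles[[s]]
    n_target <- config$n_adults[s]
    if (rect[3] <= 0 || rect[4] <= 0) stop("degenerate rectangle for subpop ", s)
    pts <- matrix(numeric(0), ncol = 2L)
    guard <- 0L
    while (nrow(pts) < n_target) {
      guard <- guard + 1L
      if (guard > 1000L)
        stop("rectangle too small for requested intensity in subpop ",
             config$subpop_labels[s])
      px <- stats::runif(cp$n_parents, rect[1], rect[1] + rect[3])
      py <- stats::runif(cp$n_parents, rect[2], rect[2] + rect[4])
      nk <- stats::rpois(cp$n_parents, cp$mean_offspring)
      if (sum(nk) == 0L) next
      cx <- rep(px, nk) + stats::rnorm(sum(nk), sd = cp$radius)
      cy <- rep(py, nk) + stats::rnorm(sum(nk), sd = cp$radius)
      keep <- cx >= rect[1] & cx <= rect[1] + rect[3] &
              cy >= rect[2] & cy <= rect[2] + rect[4]
      pts <- rbind(pts, cbind(cx[keep], cy[keep]))
    }
    pts <- pts[seq_len(n_target), , drop = FALSE]
    out[[s]] <- data.frame(id = sprintf("%s%03d", config$subpop_labels[s],
                                        seq_len(n_target)),
                           x = pts[, 1L], y = pts[, 2L],
                           subpop = config$subpop_labels[s],
                           cohort = "adult", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# founder allele frequencies: per locus, k alleles with Dirichlet(conc) freqs
# and even fragment-size codes
draw_founder_freqs <- function(config) {
  k_range <- config$alleles_per_locus
  freqs <- vector("list", config$n_loci)
  names(freqs) <- sprintf("L%02d", seq_len(config$n_loci))
  for (l in seq_len(config$n_loci)) {
    k <- sample(seq(k_range[1L], k_range[2L]), 1L)
    w <- stats::rgamma(k, shape = config$allele_freq_concentration)
    codes <- sort(sample(seq(100L, 398L, by = 2L), k))
    freqs[[l]] <- stats::setNames(w / sum(w), codes)
  }
  if (all(vapply(freqs, length, integer(1L)) < 2L))
    stop("all-monomorphic founder draw; need >= 2 alleles somewhere")
  freqs
}

# draw n HWE genotypes (n x 2 integer matrix of allele codes) from freqs
rhwe_genotypes <- function(n, p) {
  codes <- as.integer(names(p))
  a <- sample(codes, n, replace = TRUE, prob = p)
  b <- sample(codes, n, replace = TRUE, prob = p)
  cbind(pmin(a, b), pmax(a, b))
}

# Mendelian child calls: one random allele from each parent per locus
mendel_cross <- function(mom_tab, dad_tab, n_loci) {
  n <- nrow(mom_tab)
  out <- matrix(0L, n, 2L * n_loci)
  for (l in seq_len(n_loci)) {
    cm <- c(2L * l - 1L, 2L * l)
    a <- ifelse(stats::runif(n) < 0.5, mom_tab[, cm[1L]], mom_tab[, cm[2L]])
    b <- ifelse(stats::runif(n) < 0.5, dad_tab[, cm[1L]], dad_tab[, cm[2L]])
    out[, cm[1L]] <- pmin(a, b); out[, cm[2L]] <- pmax(a, b)
  }
  out
}

#' Forward-simulate generations of a mapped SSR population
#'
#' Founders get Hardy-Weinberg genotypes at Dirichlet-drawn allele
#' frequencies. Each non-overlapping generation keeps sub-population sizes
#' constant: every new adult draws a mother uniformly within its
#' sub-population, is placed at the mother plus a seed-kernel displacement
#' (rejected until inside the natal rectangle), and draws a father among all
#' adults (any sub-population, self excluded) with probability proportional
#' to the pollen kernel at the mother-father distance - unless selfed with
#' the configured probability, in which case father = mother.
#'
#' @param config a [sim_config()].
#' @param positions adult positions from [simulate_positions()]; simulated
#'   from the config when `NULL`.
#' @param seed optional integer overriding `config$rng_seed` (the RNG is reset
#'   only when `positions` is supplied, otherwise position simulation already
#'   seeded it).
#' @return list with `adults` (final-cohort [genotype_table()] with `pop` =
#'   subpop), `positions` (final cohort coordinates), and `truth` (founder
#'   frequencies, per-generation allele frequencies, final-generation pedigree
#'   with realized pollen and seed distances).
#' @export
simulate_generations <- function(config, positions = NULL, seed = config$rng_seed) {
  if (is.null(positions)) {
    positions <- simulate_positions(config, seed = seed)
  } else {
    set.seed(seed + 1L)
  }
  nL <- config$n_loci
  freqs <- draw_founder_freqs(config)
  loci <- names(freqs)
  n <- nrow(positions)
  tab <- matrix(0L, n, 2L * nL)
  for (l in seq_len(nL)) tab[, c(2L * l - 1L, 2L * l)] <-
    rhwe_genotypes(n, freqs[[l]])
  pos <- positions
  freq_by_gen <- list(observed_allele_freqs(tab, loci))
  pedigree <- NULL
  rects <- config$subpop_rectangles
  labels <- config$subpop_labels
  for (g in seq_len(config$n_generations)) {
    new_tab <- matrix(0L, n, 2L * nL)
    new_pos <- pos
    ped <- data.frame(id = character(n), mother_id = character(n),
                      father_id = character(n), seed_dist = numeric(n),
                      pollen_dist = numeric(n), selfed = logical(n),
                      stringsAsFactors = FALSE)
    row0 <- 0L
    for (s in seq_along(labels)) {
      rect <- rects[[s]]
      in_s <- which(pos$subpop == labels[s])
      n_s <- config$n_adults[s]
      for (i in seq_len(n_s)) {
        r <- row0 + i
        mi <- in_s[sample.int(length(in_s), 1L)]
        # seed displacement, rejected until inside the natal rectangle
        repeat {
          d <- kernel_rdist(config$seed_kernel, 1L)
          th <- stats::runif(1L, 0, 2 * pi)
          px <- pos$x[mi] + d * cos(th); py <- pos$y[mi] + d * sin(th)
          if (px >= rect[1] && px <= rect[1] + rect[3] &&
              py >= rect[2] && py <= rect[2] + rect[4]) break
        }
        if (stats::runif(1L) < config$selfing_rate) {
          fi <- mi
        } else {
          dd <- sqrt((pos$x - pos$x[mi])^2 + (pos$y - pos$y[mi])^2)
          w <- kernel_weight(config$pollen_kernel, dd)
          w[mi] <- 0
          fi <- sample.int(n, 1L, prob = w)
        }
        child_id <- sprintf("G%d_%s%03d", g, labels[s], i)
        mom <- tab[mi, ]; dad <- tab[fi, ]
        for (l in seq_len(nL)) {
          cm <- c(2L * l - 1L, 2L * l)
          a <- mom[cm[1L + (stats::runif(1L) < 0.5)]]
          b <- dad[cm[1L + (stats::runif(1L) < 0.5)]]
          new_tab[r, cm] <- c(min(a, b), max(a, b))
        }
        new_pos$x[r] <- px; new_pos$y[r] <- py
        new_pos$id[r] <- child_id
        new_pos$subpop[r] <- labels[s]
        ped$id[r] <- child_id
        ped$mother_id[r] <- pos$id[mi]
        ped$father_id[r] <- pos$id[fi]
        ped$seed_dist[r] <- sqrt((px - pos$x[mi])^2 + (py - pos$y[mi])^2)
        ped$pollen_dist[r] <- sqrt((pos$x[fi] - pos$x[mi])^2 +
                                   (pos$y[fi] - pos$y[mi])^2)
        ped$selfed[r] <- fi == mi
      }
      row0 <- row0 + n_s
    }
    tab <- new_tab
    pos <- new_pos
    pedigree <- ped
    freq_by_gen <- c(freq_by_gen, list(observed_allele_freqs(tab, loci)))
  }
  adults <- genotype_table(tab, loci, samples = pos$id, pop = pos$subpop)
  list(adults = adults, positions = pos,
       truth = list(founder_freqs = freqs, freq_by_generation = freq_by_gen,
                    pedigree = pedigree))
}

# allele frequencies straight from a call matrix (internal; the diversity
# module has the user-facing version on genotype_table)
observed_allele_freqs <- function(tab, loci) {
  out <- vector("list", length(loci)); names(out) <- loci
  for (l in seq_along(loci)) {
    v <- c(tab[, 2L * l - 1L], tab[, 2L * l])
    v <- v[v > 0L]
    tb <- table(v)
    out[[l]] <- stats::setNames(as.numeric(tb) / sum(tb), names(tb))
  }
  out
}

#' Simulate progeny arrays (capsules) from mapped adults
#'
#' Each capsule has a known mother and, in single-donor mode, exactly one
#' outcross father drawn by the pollen kernel over all other adults; every
#' outcrossed offspring of the capsule is then sired by that father (the
#' pollinium model). With `n_donors = k > 1`, k fathers are drawn and each
#' offspring picks one uniformly (equal shares). Each offspring is
#' independently selfed (father = mother) with probability
#' `config$selfing_rate`.
#'
#' @param config a [sim_config()].
#' @param adults adult [genotype_table()].
#' @param positions adult coordinates (`id, x, y`).
#' @param seed optional integer overriding `config$rng_seed`.
#' @return list: `arrays` (capsule_id, mother_id, offspring_id), `offspring`
#'   ([genotype_table()]), `truth` (per-offspring true father id and per-capsule
#'   donor set with mother-father distances).
#' @export
simulate_progeny_arrays <- function(config, adults, positions,
                                    seed = config$rng_seed) {
  set.seed(seed + 2L)
  caps <- config$capsules
  n_caps <- caps$n
  sizes <- rep_len(as.integer(caps$sizes), n_caps)
  if (identical(caps$mothers, "random")) {
    if (n_caps > length(adults$samples))
      stop("requested more capsule mothers than available adults")
    mothers <- sample(adults$samples, n_caps)
  } else {
    mothers <- rep_len(as.character(caps$mothers), n_caps)
    if (!all(mothers %in% adults$samples))
      stop("unknown capsule mother id")
  }
  nL <- length(adults$loci)
  idx <- match(adults$samples, positions$id)
  if (anyNA(idx)) stop("adult missing coordinates")
  px <- positions$x[idx]; py <- positions$y[idx]
  map_rows <- vector("list", n_caps)
  gt_rows <- vector("list", n_caps)
  truth_off <- vector("list", n_caps)
  donors <- vector("list", n_caps)
  for (c_i in seq_len(n_caps)) {
    cap_id <- sprintf("CAP%02d", c_i)
    mi <- match(mothers[c_i], adults$samples)
    dd <- sqrt((px - px[mi])^2 + (py - py[mi])^2)
    w <- kernel_weight(config$pollen_kernel, dd)
    w[mi] <- 0
    k <- max(1L, config$n_donors)
    f_idx <- sample.int(length(w), k, prob = w)
    donors[[c_i]] <- data.frame(capsule_id = cap_id,
                                father_id = adults$samples[f_idx],
                                distance_m = dd[f_idx],
                                stringsAsFactors = FALSE)
    n_off <- sizes[c_i]
    selfed <- stats::runif(n_off) < config$selfing_rate
    pick <- f_idx[sample.int(k, n_off, replace = TRUE)]
    pick[selfed] <- mi
    mom_tab <- adults$tab[rep(mi, n_off), , drop = FALSE]
    dad_tab <- adults$tab[pick, , drop = FALSE]
    kid_tab <- mendel_cross(mom_tab, dad_tab, nL)
    ids <- sprintf("%s_O%03d", cap_id, seq_len(n_off))
    map_rows[[c_i]] <- data.frame(capsule_id = cap_id,
                                  mother_id = mothers[c_i],
                                  offspring_id = ids,
                                  stringsAsFactors = FALSE)
    rownames(kid_tab) <- ids
    gt_rows[[c_i]] <- kid_tab
    truth_off[[c_i]] <- data.frame(offspring_id = ids,
                                   father_id = adults$samples[pick],
                                   selfed = selfed,
                                   stringsAsFactors = FALSE)
  }
  off_tab <- do.call(rbind, gt_rows)
  offspring <- genotype_table(off_tab, adults$loci,
                              samples = rownames(off_tab),
                              pop = rep(sprintf("CAP%02d", seq_len(n_caps)),
                                        sizes))
  if (config$genotyping_error_rate > 0)
    offspring <- apply_genotyping_error(offspring,
                                        config$genotyping_error_rate)
  if (config$missing_rate > 0) {
    tb <- offspring$tab
    drop <- matrix(stats::runif(length(adults$loci) * nrow(tb)) <
                     config$missing_rate, nrow(tb))
    for (l in seq_along(adults$loci)) {
      cm <- c(2L * l - 1L, 2L * l)
      tb[drop[, l], cm] <- 0L
    }
    offspring <- genotype_table(tb, adults$loci, rownames(tb), offspring$pop)
  }
  list(arrays = do.call(rbind, map_rows), offspring = offspring,
       truth = list(offspring = do.call(rbind, truth_off),
                    donors = do.call(rbind, donors)))
}

#' Apply random mistyping to a genotype table
#'
#' Each single allele slot is independently replaced, with the given
#' probability, by a random allele drawn from the table's observed allele
#' frequencies at that locus. Missing calls are untouched.
#'
#' @param gt a [genotype_table()].
#' @param rate per-slot mistyping probability in `[0, 1]`.
#' @param seed optional seed.
#' @return a new `genotype_table`.
#' @export
apply_genotyping_error <- function(gt, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(gt)
  tab <- gt$tab
  freqs <- observed_allele_freqs(tab, gt$loci)
  for (l in seq_along(gt$loci)) {
    p <- freqs[[l]]
    codes <- as.integer(names(p))
    for (cc in c(2L * l - 1L, 2L * l)) {
      hit <- which(tab[, cc] > 0L & stats::runif(nrow(tab)) < rate)
      if (length(hit))
        tab[hit, cc] <- sample(codes, length(hit), replace = TRUE, prob = p)
    }
    cm <- c(2L * l - 1L, 2L * l)
    lo <- pmin(tab[, cm[1L]], tab[, cm[2L]])
    hi <- pmax(tab[, cm[1L]], tab[, cm[2L]])
    tab[, cm[1L]] <- lo; tab[, cm[2L]] <- hi
  }
  genotype_table(tab, gt$loci, gt$samples, gt$pop)
}

#' Simulate a complete dataset (files plus hidden truth)
#'
#' Convenience wrapper running [simulate_positions()],
#' [simulate_generations()] and [simulate_progeny_arrays()] under one config,
#' optionally writing `genotypes.csv`, `coords.csv`, `arrays.csv`,
#' `offspring.csv` and `truth.json` to a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list `adults`, `positions`, `arrays`, `offspring`, `truth`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  pos <- simulate_positions(config)
  gen <- simulate_generations(config, positions = pos, seed = config$rng_seed)
  arr <- simulate_progeny_arrays(config, gen$adults, gen$positions)
  res <- list(adults = gen$adults, positions = gen$positions,
              arrays = arr$arrays, offspring = arr$offspring,
              truth = c(gen$truth, arr$truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotype_csv(res$adults, file.path(out_dir, "genotypes.csv"))
    write_coords_csv(res$positions, file.path(out_dir, "coords.csv"))
    write_arrays_csv(res$arrays, file.path(out_dir, "arrays.csv"))
    write_genotype_csv(res$offspring, file.path(out_dir, "offspring.csv"))
    jsonlite::write_json(res$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
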