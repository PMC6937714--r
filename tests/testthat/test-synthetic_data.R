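test_that("a fixed seed gives bit-identical simulations", {
  s1 <- small_sim(seed = 7)
  s2 <- small_sim(seed = 7)
  expect_identical(s1$adults$tab, s2$adults$tab)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$offspring$tab, s2$offspring$tab)
  expect_identical(s1$truth$pedigree, s2$truth$pedigree)
  s3 <- small_sim(seed = 8)
  expect_false(identical(s1$adults$tab, s3$adults$tab))
})

test_that("sub-population rectangles keep > 100 m separation", {
  cfg <- sim_config()
  pos <- simulate_positions(cfg, seed = 3)
  sp <- split(pos[, c("x", "y")], pos$subpop)
  labs <- names(sp)
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i >= j) next
    dmin <- min(as.matrix(stats::dist(rbind(sp[[i]], sp[[j]])))[
      seq_len(nrow(sp[[i]])), nrow(sp[[i]]) + seq_len(nrow(sp[[j]]))])
    expect_gt(dmin, 100)
  }
  # declared counts respected, points inside rectangles
  expect_equal(as.integer(table(pos$subpop)[cfg$subpop_labels]),
               cfg$n_adults)
  for (s in seq_len(cfg$n_subpops)) {
    r <- cfg$subpop_rectangles[[s]]
    p <- pos[pos$subpop == cfg$subpop_labels[s], ]
    expect_true(all(p$x >= r[1] & p$x <= r[1] + r[3] &
                    p$y >= r[2] & p$y <= r[2] + r[4]))
  }
})

test_that("offspring alleles come from their recorded parents (error 0)", {
  sim <- small_sim(seed = 2)
  ped <- sim$truth$offspring  # progeny-array truth
  adults <- sim$adults
  for (i in sample(nrow(ped), 50)) {
    off <- sim$offspring$tab[match(ped$offspring_id[i],
                                   sim$offspring$samples), ]
    mom_id <- sim$arrays$mother_id[match(ped$offspring_id[i],
                                         sim$arrays$offspring_id)]
    mom <- adults$tab[match(mom_id, adults$samples), ]
    dad <- adults$tab[match(ped$father_id[i], adults$samples), ]
    for (l in seq_along(adults$loci)) {
      cm <- c(2L * l - 1L, 2L * l)
      expect_true(all(off[cm] %in% c(mom[cm], dad[cm])))
    }
  }
  # generation pedigree closure
  gen <- simulate_generations(sim_config(n_generations = 1, rng_seed = 5))
  ped <- gen$truth$pedigree
  expect_true(all(table(ped$id) == 1L))  # exactly one father per offspring
})

test_that("selfed generations inflate homozygosity as expected", {
  # s = 1: observed heterozygosity should drop ~50% per generation
  cfg <- sim_config(selfing_rate = 1, n_generations = 4,
                    alleles_per_locus = c(4L, 8L), rng_seed = 11)
  gen <- simulate_generations(cfg)
  ls4 <- locus_summary(gen$adults)
  expect_lt(mean(ls4$Ho, na.rm = TRUE), 0.15)
  expect_gt(mean(ls4$Fis, na.rm = TRUE), 0.5)
})

test_that("genotyping error behaves like per-slot resampling", {
  gt <- random_gt(n = 150, L = 6, k = 4, missing_rate = 0.1)
  expect_identical(apply_genotyping_error(gt, 0)$tab, gt$tab)
  # rate 1: every typed slot redrawn; expected unchanged fraction = sum p^2
  set.seed(9)
  gt2 <- apply_genotyping_error(gt, 1, seed = 99)
  typed <- gt$tab > 0L
  expect_identical(gt2$tab == 0L, gt$tab == 0L)  # missing untouched
  # per-locus expected fraction changed (up to re-sorting of pairs)
  freqs <- allele_frequencies(gt)
  exp_changed <- mean(sapply(freqs, function(p) 1 - sum(p^2)))
  sets_differ <- sapply(seq_along(gt$loci), function(l) {
    cm <- c(2L * l - 1L, 2L * l)
    rowSums(gt$tab[, cm] != gt2$tab[, cm]) > 0
  })
  # P(pair unchanged) >= (sum p^2)^2; crude band around expectation
  obs <- mean(sets_differ[gt$tab[, seq(1, 12, 2)] > 0])
  expect_gt(obs, exp_changed^1.5)
  expect_lt(obs, 1)
  # expected number of altered slots at the study error rate
  big <- random_gt(n = 1100, L = 15, k = 6, missing_rate = 0)
  big2 <- apply_genotyping_error(big, 0.012, seed = 4)
  n_hit_bound <- 1100 * 15 * 2 * 0.012  # binomial mean of touched slots
  changed <- sum(big$tab != big2$tab)
  expect_lt(changed, n_hit_bound + 4 * sqrt(n_hit_bound))
})

test_that("progeny arrays honour family sizes and single-donor capsules", {
  sizes <- c(189L, 182L, 187L, 56L, 181L, 169L, 24L, 112L)
  cfg <- sim_config(n_generations = 1,
                    capsules = list(n = 8, sizes = sizes,
                                    mothers = "random"),
                    rng_seed = 21)
  sim <- simulate_dataset(cfg)
  expect_equal(as.integer(table(sim$arrays$capsule_id)[
    sprintf("CAP%02d", 1:8)]), sizes)
  # single-donor: one father per capsule in the truth record
  fathers <- tapply(sim$truth$offspring$father_id,
                    sub("_O.*", "", sim$truth$offspring$offspring_id),
                    function(x) length(unique(x)))
  expect_true(all(fathers == 1L))
  # multi-donor mode: k distinct fathers available
  cfg5 <- sim_config(n_generations = 1, n_donors = 5L,
                     capsules = list(n = 4, sizes = 200L,
                                     mothers = "random"),
                     rng_seed = 22)
  sim5 <- simulate_dataset(cfg5)
  fathers5 <- tapply(sim5$truth$offspring$father_id,
                     sub("_O.*", "", sim5$truth$offspring$offspring_id),
                     function(x) length(unique(x)))
  expect_true(all(fathers5 >= 4L))
  expect_error(simulate_progeny_arrays(
    sim_config(capsules = list(n = 500, sizes = 5, mothers = "random")),
    sim$adults, sim$positions), "more capsule mothers")
})

test_that("clustered positions register as aggregated, CSR limit as random", {
  cfg <- sim_config(n_subpops = 1L,
                    subpop_rectangles = list(c(0, 0, 140, 120)),
                    subpop_labels = "A", n_adults = 60L,
                    cluster_process = list(n_parents = 10L,
                                           mean_offspring = 10, radius = 5),
                    rng_seed = 31)
  pos <- simulate_positions(cfg)
  o <- o_ring_analysis(pos, window = c(0, 0, 140, 120), max_r = 15,
                       n_sim = 99, seed = 1)
  expect_gt(sum(o$classification[1:10] == "aggregated"), 3)
  # huge cluster radius: indistinguishable from CSR
  cfg2 <- sim_config(n_subpops = 1L,
                     subpop_rectangles = list(c(0, 0, 140, 120)),
                     subpop_labels = "A", n_adults = 60L,
                     cluster_process = list(n_parents = 10L,
                                            mean_offspring = 10,
                                            radius = 400),
                     rng_seed = 32)
  pos2 <- simulate_positions(cfg2)
  o2 <- o_ring_analysis(pos2, window = c(0, 0, 140, 120), max_r = 15,
                        n_sim = 99, seed = 2)
  expect_gt(mean(o2$classification == "random"), 0.8)
})

test_that("father sampling follows the pollen kernel weights", {
  # explicit check of the sampling distribution on a fixed geometry:
  # 1 mother, candidate fathers at known distances, exponential kernel
  cfg <- sim_config(n_subpops = 1L,
                    subpop_rectangles = list(c(0, 0, 1000, 50)),
                    subpop_labels = "A", n_adults = 5L,
                    pollen_kernel = list(family = "exponential", scale = 100),
                    n_generations = 1L,
                    capsules = list(n = 1, sizes = 1, mothers = "A001"),
                    rng_seed = 41)
  pos <- data.frame(id = sprintf("A%03d", 1:5),
                    x = c(0, 50, 100, 200, 400), y = 0,
                    subpop = "A", cohort = "adult")
  adults <- random_gt(n = 5, L = 2, missing_rate = 0)
  adults$samples <- pos$id
  rownames(adults$tab) <- pos$id
  w <- exp(-c(50, 100, 200, 400) / 100)
  p_exp <- w / sum(w)
  set.seed(5)
  draws <- replicate(4000, {
    arr <- simulate_progeny_arrays(cfg, adults, pos,
                                   seed = sample.int(1e6, 1))
    arr$truth$donors$father_id
  })
  p_obs <- as.numeric(table(factor(draws, levels = pos$id[-1])) / 4000)
  expect_lt(max(abs(p_obs - p_exp)), 4 * sqrt(0.25 / 4000) + 0.02)
})
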