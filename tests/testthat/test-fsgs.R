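test_that("kinship matches closed-form values for constructed pairs", {
  # background of 98 individuals at ~HWE plus one clone pair, biallelic
  set.seed(12)
  n <- 100
  a <- sample(1:2, n, TRUE); b <- sample(1:2, n, TRUE)
  tab <- cbind(pmin(a, b), pmax(a, b))
  tab[1, ] <- c(1L, 1L); tab[2, ] <- c(1L, 1L)   # identical homozygotes
  tab[3, ] <- c(1L, 2L); tab[4, ] <- c(1L, 2L)   # identical heterozygotes
  gt <- genotype_table(tab, "L1")
  kin <- pairwise_kinship(gt)
  p <- as.numeric(allele_frequencies(gt)$L1)
  den <- sum(p * (1 - p))
  bias <- den / (n - 1)
  # identical homozygotes AA: numerator = 2 (1-pA)^2 ... expanded dosages
  x_hom <- c(1, 0) - p
  expect_equal(kin$F[1, 2], (sum(x_hom^2) + bias) / den, tolerance = 1e-12)
  # identical heterozygotes: centred dosages (0.5-pA, 0.5-pB)
  x_het <- c(0.5, 0.5) - p
  expect_equal(kin$F[3, 4], (sum(x_het^2) + bias) / den, tolerance = 1e-12)
  # averaged over the HWE genotype mix, clone kinship ~ 0.5 at p = 0.5
  set.seed(13)
  tab2 <- NULL
  for (i in 1:60) {
    g <- sort(sample(1:2, 2, TRUE))
    tab2 <- rbind(tab2, g, g)  # 60 clone pairs
  }
  gt2 <- genotype_table(tab2, "L1", samples = sprintf("c%03d", 1:120))
  k2 <- pairwise_kinship(gt2)
  clone_vals <- k2$F[cbind(seq(1, 119, 2), seq(2, 120, 2))]
  expect_gt(mean(clone_vals), 0.38)
  expect_lt(mean(clone_vals), 0.62)
})

test_that("population-wide mean kinship matches the analytic centring", {
  set.seed(14)
  gt <- random_gt(n = 40, L = 6, k = 5, missing_rate = 0)
  kin <- pairwise_kinship(gt)
  up <- upper.tri(kin$F)
  expect_lt(abs(mean(kin$F[up])), 2 / (40 - 1))
  # exact finite-sample mean for one locus against sample frequencies:
  # mean numerator = -sum_i ||x_i - p||^2 / (n (n-1)) + bias
  f1 <- allele_frequencies(gt)[1]
  k1 <- pairwise_kinship(gt, freq_reference = NULL)
  p <- as.numeric(f1$L1)
  m <- gt$tab[, 1:2]
  X <- matrix(0, 40, length(p))
  codes <- as.integer(names(f1$L1))
  for (i in 1:40) for (s in 1:2)
    X[i, match(m[i, s], codes)] <- X[i, match(m[i, s], codes)] + 0.5
  Xc <- sweep(X, 2, p)
  mean_num <- -sum(Xc^2) / (40 * 39) + sum(p * (1 - p)) / 39
  num_obs <- k1$num[, , 1][upper.tri(k1$num[, , 1])]
  expect_equal(mean(num_obs), mean_num, tolerance = 1e-10)
})

test_that("parent-offspring kinship averages near 0.25 in simulations", {
  set.seed(15)
  vals <- c()
  for (s in 1:2) {
    sim <- small_sim(seed = 200 + s, sizes = rep(12, 8), gens = 1)
    # pool mothers and offspring; reference frequencies from adults
    ids <- unique(sim$arrays$mother_id)
    comb <- genotype_table(rbind(sim$adults$tab,
                                 sim$offspring$tab),
                           sim$adults$loci,
                           samples = c(sim$adults$samples,
                                       sim$offspring$samples))
    kin <- pairwise_kinship(comb,
                            freq_reference = allele_frequencies(sim$adults))
    mi <- match(sim$arrays$mother_id, comb$samples)
    oi <- match(sim$arrays$offspring_id, comb$samples)
    vals <- c(vals, kin$F[cbind(mi, oi)])
  }
  expect_gt(mean(vals), 0.18)
  expect_lt(mean(vals), 0.32)
})

test_that("correlogram bookkeeping conserves pairs and weights", {
  set.seed(16)
  sim <- simulate_generations(sim_config(n_generations = 1, rng_seed = 61))
  kin <- pairwise_kinship(sim$adults)
  corr <- suppressMessages(
    kinship_correlogram(kin, sim$positions, n_perm = 49, seed = 1))
  n <- length(kin$samples)
  expect_equal(sum(corr$n_pairs) + corr$n_dropped, n * (n - 1) / 2)
  # pair-count-weighted class means reconstruct the global mean
  ok <- corr$n_pairs > 0
  up <- upper.tri(kin$F)
  D <- as.matrix(dist(sim$positions[match(kin$samples, sim$positions$id),
                                    c("x", "y")]))
  keep <- D[up] <= max(corr$edges)
  expect_equal(sum(corr$F_mean[ok] * corr$n_pairs[ok]) / sum(corr$n_pairs),
               mean(kin$F[up][keep]), tolerance = 1e-10)
  # classes are half-open (lo, hi]: a pair at exactly 5 m goes to class 1
  kin2 <- pairwise_kinship(make_gt(list(c(1L, 2L), c(1L, 2L), c(1L, 1L)),
                                   samples = c("a", "b", "c")))
  co <- data.frame(id = c("a", "b", "c"), x = c(0, 5, 100), y = 0)
  cg <- kinship_correlogram(kin2, co, n_perm = 0)
  expect_equal(cg$n_pairs[1], 1L)
})

test_that("type-I error of the permutation envelope is near nominal", {
  set.seed(17)
  hits <- c(); tot <- 0
  sim <- simulate_generations(sim_config(n_generations = 1, rng_seed = 71))
  kin <- pairwise_kinship(sim$adults)
  for (r in 1:12) {
    # break any genotype-location association by shuffling coordinates
    pos <- sim$positions
    pos[, c("x", "y")] <- pos[sample.int(nrow(pos)), c("x", "y")]
    corr <- suppressMessages(
      kinship_correlogram(kin, pos, n_perm = 99, seed = r))
    ok <- corr$n_pairs > 0
    hits <- c(hits, sum(corr$significant[ok])); tot <- tot + sum(ok)
  }
  expect_lt(sum(hits) / tot, 0.15)
})

test_that("slope, jackknife and Sp follow their defining arithmetic", {
  set.seed(18)
  sim <- simulate_generations(sim_config(rng_seed = 81))
  kin <- pairwise_kinship(sim$adults)
  sl <- slope_and_sp(kin, sim$positions)
  # Sp identity from the returned slope and first-class mean kinship
  expect_equal(sl$Sp, -sl$b_LF / (1 - sl$F1), tolerance = 1e-12)
  expect_equal(sl$ci, sl$b_LF + c(-1.96, 1.96) * sl$se_jack)
  expect_gte(sl$se_jack, 0)
  # worked numbers: b = -0.01, F1 = 0.05
  expect_equal(-(-0.01) / (1 - 0.05), 0.010526, tolerance = 1e-4)
  # slope invariant to uniform rescaling of coordinates
  pos2 <- sim$positions
  pos2$x <- pos2$x * 3.7; pos2$y <- pos2$y * 3.7
  sl2 <- slope_and_sp(kin, pos2)
  expect_equal(sl2$b_LF, sl$b_LF, tolerance = 1e-10)
})

test_that("cubic residual curvature recovers planted coefficients", {
  d <- c(2.5, 7, 12, 17, 25, 35, 45, 75, 125)
  ld <- log(d)
  corr <- structure(list(d_mean = d,
                         F_mean = 0.01 - 0.002 * ld + 0.02 * ld^2 +
                           0.001 * ld^3,
                         n_pairs = rep(10L, length(d))),
                    class = "correlogram")
  cur <- residual_curvature(corr)
  expect_equal(unname(cur$coef[c("c2", "c3")]), c(0.02, 0.001),
               tolerance = 1e-8)
  expect_equal(cur$k, 2 * 0.02 + 6 * 0.001 * log(2.5), tolerance = 1e-8)
  expect_equal(cur$verdict, "seed_restricted")
  # worked numbers: c2 = 0.02, c3 = 0.001, d1 = 5 -> k = 0.0497 > 0
  expect_equal(2 * 0.02 + 6 * 0.001 * log(5), 0.0496566, tolerance = 1e-6)
  # exactly linear residuals: c2 = c3 = 0, k = 0
  corr0 <- structure(list(d_mean = d, F_mean = 0.03 - 0.004 * ld,
                          n_pairs = rep(10L, length(d))),
                     class = "correlogram")
  cur0 <- residual_curvature(corr0)
  expect_equal(cur0$k, 0, tolerance = 1e-10)
  expect_equal(cur0$verdict, "pollen_restricted_or_neutral")
  expect_error(residual_curvature(structure(list(d_mean = d[1:3],
                                                 F_mean = rep(0, 3)),
                                            class = "correlogram")),
               ">= 5")
})

test_that("Sp grows as seed dispersal tightens (sigma_s 2 vs 200 m)", {
  sp_of <- function(ss, seed) {
    cfg <- sim_config(seed_kernel = list(family = "exponential", scale = ss),
                      n_generations = 4, rng_seed = seed)
    sim <- simulate_generations(cfg)
    kin <- pairwise_kinship(sim$adults)
    slope_and_sp(kin, sim$positions)$Sp
  }
  sp_tight <- sapply(1:3, function(s) sp_of(2, 300 + s))
  sp_loose <- sapply(1:3, function(s) sp_of(200, 300 + s))
  expect_gt(mean(sp_tight), mean(sp_loose))
})
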