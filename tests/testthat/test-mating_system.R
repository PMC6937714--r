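test_that("offspring with non-maternal alleles force t_m = 1", {
  sim <- small_sim(seed = 51, sizes = rep(40, 4), s = 0)
  arr <- progeny_arrays(sim$arrays, sim$adults, sim$offspring)
  fit <- fit_mixed_mating(arr, check_monotone = TRUE)
  expect_gte(fit$pooled$t_m, 0.999)
  expect_true(all(fit$families$t_m >= 0.995))
  expect_true(all(fit$families$converged))
})

test_that("single-locus pure selfing gives t near 0 (grid-search oracle)", {
  # mother AB at a locus with p_A = 0.9; offspring counts exactly match the
  # selfing expectation (AA:AB:BB = 1:2:1), which differs from the outcross
  # expectation (0.45, 0.50, 0.05)
  adults <- make_gt(list(c(1L, 2L), c(1L, 1L)), samples = c("M", "X"))
  offs <- c(rep(list(c(1L, 1L)), 25), rep(list(c(1L, 2L)), 50),
            rep(list(c(2L, 2L)), 25))
  off_gt <- make_gt(offs, samples = sprintf("o%03d", 1:100))
  mapping <- data.frame(capsule_id = "C1", mother_id = "M",
                        offspring_id = off_gt$samples)
  arr <- progeny_arrays(mapping, adults, off_gt)
  freqs <- list(L1 = c(`1` = 0.9, `2` = 0.1))
  fit <- fit_mixed_mating(arr, freqs = freqs)
  # independent oracle: 1-parameter grid over the mixture likelihood
  a_probs <- c(AA = 0.25, AB = 0.5, BB = 0.25)
  b_probs <- c(AA = 0.45, AB = 0.5, BB = 0.05)
  counts <- c(AA = 25, AB = 50, BB = 25)
  grid <- seq(0, 1, by = 1e-4)
  ll <- sapply(grid, function(t)
    sum(counts * log((1 - t) * a_probs + t * b_probs)))
  t_grid <- grid[which.max(ll)]
  expect_lt(t_grid, 0.01)
  # the EM crawls towards the boundary MLE (its step ratio -> 1 there)
  expect_lt(abs(fit$pooled$t_m - t_grid), 0.01)
})

test_that("selfing-rate recovery and t_s behaviour under mixed mating", {
  sim <- small_sim(seed = 52, sizes = rep(80, 6), s = 0.4)
  arr <- progeny_arrays(sim$arrays, sim$adults, sim$offspring)
  fit <- fit_mixed_mating(arr, check_monotone = TRUE)
  # sharp oracle: the realized selfing fraction recorded by the simulator
  expect_equal(1 - fit$pooled$t_m, mean(sim$truth$offspring$selfed),
               tolerance = 0.02)
  expect_lt(abs(1 - fit$pooled$t_m - 0.4), 0.1)
  # t_s is an average of per-locus MLEs and may lie outside [0, 1];
  # here it should land near t_m
  expect_equal(fit$pooled$t_s, fit$pooled$t_m, tolerance = 0.25)
})

test_that("correlated paternity equals the share-square oracle", {
  # constructed pedigree: offspring fathers drawn i.i.d. with known shares
  set.seed(53)
  n_adults <- 60
  adults <- random_gt(n = n_adults, L = 12, k = 6, missing_rate = 0)
  mom <- 1L
  make_family <- function(fathers, n_off, cap) {
    picks <- sample(fathers, n_off, replace = TRUE)
    kid <- matrix(0L, n_off, ncol(adults$tab))
    for (i in seq_len(n_off)) {
      for (l in seq_len(12)) {
        cm <- c(2L * l - 1L, 2L * l)
        a <- adults$tab[mom, cm][1 + (runif(1) < .5)]
        b <- adults$tab[picks[i], cm][1 + (runif(1) < .5)]
        kid[i, cm] <- c(min(a, b), max(a, b))
      }
    }
    rownames(kid) <- sprintf("%s_%03d", cap, seq_len(n_off))
    list(kid = kid, picks = picks)
  }
  # two equal donors: r_p = 0.5, N_ep = 2
  fams <- lapply(1:4, function(j) make_family(c(2L, 3L), 60, paste0("K", j)))
  off_tab <- do.call(rbind, lapply(fams, `[[`, "kid"))
  off_gt <- genotype_table(off_tab, adults$loci, rownames(off_tab))
  mapping <- data.frame(capsule_id = rep(sprintf("K%d", 1:4), each = 60),
                        mother_id = adults$samples[mom],
                        offspring_id = rownames(off_tab))
  arr <- progeny_arrays(mapping, adults, off_gt)
  cp <- correlated_paternity(arr)
  # oracle: realized share-square probability of sharing a father
  shares <- sapply(fams, function(f) {
    tb <- table(f$picks) / length(f$picks); sum(tb^2)
  })
  expect_equal(cp$r_pm, mean(shares), tolerance = 0.15)
  expect_equal(cp$N_ep, 2, tolerance = 0.3)
  # many donors: r_p small, N_ep large
  fams50 <- lapply(1:4, function(j)
    make_family(2:51, 60, paste0("W", j)))
  off_tab50 <- do.call(rbind, lapply(fams50, `[[`, "kid"))
  off50 <- genotype_table(off_tab50, adults$loci, rownames(off_tab50))
  map50 <- data.frame(capsule_id = rep(sprintf("W%d", 1:4), each = 60),
                      mother_id = adults$samples[mom],
                      offspring_id = rownames(off_tab50))
  cp50 <- correlated_paternity(progeny_arrays(map50, adults, off50))
  expect_lt(cp50$r_pm, 0.12)
  expect_gt(cp50$N_ep, 10)
})

test_that("single-donor capsules give N_ep at the boundary", {
  sim <- small_sim(seed = 54, sizes = rep(50, 5), s = 0, n_donors = 1)
  arr <- progeny_arrays(sim$arrays, sim$adults, sim$offspring)
  cp <- correlated_paternity(arr)
  expect_equal(cp$N_ep, 1, tolerance = 0.02)
  # r_ps is a noisier per-locus average; only near-zero difference expected
  expect_lt(abs(cp$r_ps_minus_r_pm), 0.15)
})

test_that("family bootstrap is seedable and degenerates correctly", {
  # identical families: SE exactly 0
  adults <- make_gt(list(c(1L, 2L), c(3L, 4L)), samples = c("M", "X"))
  off <- make_gt(rep(list(c(1L, 3L)), 12), samples = sprintf("o%02d", 1:12))
  mapping <- data.frame(capsule_id = rep(c("C1", "C2"), each = 6),
                        mother_id = "M",
                        offspring_id = off$samples)
  arr <- progeny_arrays(mapping, adults, off)
  bs <- bootstrap_families(arr, "mixed_mating", n_boot = 20, seed = 1)
  expect_equal(unname(bs$se["t_m"]), 0)
  # same seed, same SEs; different seed differs on a non-degenerate fit
  sim <- small_sim(seed = 55, sizes = rep(30, 5), s = 0.3)
  arr2 <- progeny_arrays(sim$arrays, sim$adults, sim$offspring)
  b1 <- bootstrap_families(arr2, "mixed_mating", n_boot = 30, seed = 7)
  b2 <- bootstrap_families(arr2, "mixed_mating", n_boot = 30, seed = 7)
  expect_identical(b1$se, b2$se)
  expect_gt(b1$se[["t_m"]], 0)
  expect_error(bootstrap_families(
    progeny_arrays(mapping[mapping$capsule_id == "C1", ], adults, off),
    "mixed_mating"), ">= 2 families")
})

test_that("bootstrap SE shrinks roughly as families accumulate", {
  sim_many <- small_sim(seed = 56, sizes = rep(25, 16), s = 0.3)
  arr16 <- progeny_arrays(sim_many$arrays, sim_many$adults,
                          sim_many$offspring)
  arr4 <- arr16
  keep <- arr16$capsules$capsule_id[1:4]
  arr4$capsules <- arr16$capsules[1:4, ]
  arr4$mapping <- arr16$mapping[arr16$mapping$capsule_id %in% keep, ]
  se16 <- bootstrap_families(arr16, "mixed_mating", n_boot = 60,
                             seed = 3)$se[["t_m"]]
  se4 <- bootstrap_families(arr4, "mixed_mating", n_boot = 60,
                            seed = 3)$se[["t_m"]]
  expect_lt(se16, se4 * 1.2)
})
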