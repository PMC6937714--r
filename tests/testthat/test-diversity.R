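test_that("allele frequencies exclude missing calls and sum to one", {
  gt <- make_gt(list(c(1L, 1L), c(1L, 2L), c(2L, 2L)))
  f <- allele_frequencies(gt)
  expect_equal(as.numeric(f$L1), c(0.5, 0.5))
  gt2 <- make_gt(list(c(1L, 1L), c(0L, 0L)))
  f2 <- allele_frequencies(gt2)
  expect_equal(as.numeric(f2$L1), 1)
  expect_equal(attr(f2$L1, "n_typed"), 1L)
  set.seed(1)
  for (r in 1:3) {
    g <- random_gt(missing_rate = 0.3)
    expect_true(all(abs(sapply(allele_frequencies(g), sum) - 1) < 1e-12))
  }
})

test_that("locus summaries match closed forms", {
  # two alleles at 0.5/0.5, all heterozygotes
  gt <- make_gt(rep(list(c(1L, 2L)), 10))
  s <- locus_summary(gt)
  expect_equal(s$Ne, 2)
  expect_equal(s$I, log(2))
  expect_equal(s$Ho, 1)
  expect_equal(s$He, 0.5)
  expect_equal(s$Fis, -1)
  # monomorphic locus
  gm <- make_gt(rep(list(c(3L, 3L)), 6))
  sm <- locus_summary(gm)
  expect_equal(sm[, c("Na", "Ne", "I", "He", "Fis")],
               data.frame(Na = 1L, Ne = 1, I = 0, He = 0, Fis = 0))
  expect_equal(attr(sm, "monomorphic"), "L1")
  # frequencies (0.5, 0.25, 0.25): Ne = 1/0.375, I = 1.0397
  gt3 <- make_gt(list(c(1L, 1L), c(2L, 3L)))
  s3 <- locus_summary(gt3)
  expect_equal(s3$Ne, 1 / 0.375, tolerance = 1e-12)
  expect_equal(s3$I, -sum(c(.5, .25, .25) * log(c(.5, .25, .25))),
               tolerance = 1e-12)
  # algebraic identities on random tables: Ne = 1/(1 - He), I >= ln Ne
  set.seed(2)
  for (r in 1:5) {
    g <- random_gt(n = 30, L = 5, k = sample(2:6, 1), missing_rate = 0.1)
    s <- locus_summary(g)
    expect_equal(s$Ne, 1 / (1 - s$He), tolerance = 1e-12)
    expect_true(all(s$I >= log(s$Ne) - 1e-12))
  }
  # Nei unbiased variant scales He by 2n/(2n-1)
  su <- locus_summary(gt, unbiased = TRUE)
  expect_equal(su$He, 0.5 * 20 / 19)
})

test_that("Markov-chain HWE test agrees with exact enumeration", {
  # extreme heterozygote deficit: AA=5, AB=0, BB=5
  gt <- make_gt(c(rep(list(c(1L, 1L)), 5), rep(list(c(2L, 2L)), 5)))
  p_enum <- hwe_exact_enum(gt_subset(gt, 1:10)$tab[, 1:2])
  expect_lt(p_enum, 0.01)
  res <- hwe_test(gt, 1, dememorization = 2000, batches = 50,
                  iterations = 2000, seed = 1)
  expect_lt(abs(res$p - p_enum), max(3 * res$se, 0.003))
  # random small tables, 2-3 alleles
  set.seed(33)
  for (r in 1:4) {
    g <- random_gt(n = sample(8:20, 1), L = 1, k = sample(2:3, 1),
                   missing_rate = 0)
    m <- g$tab[, 1:2]
    if (length(unique(c(m))) < 2) next
    p_enum <- hwe_exact_enum(m)
    res <- hwe_test(g, 1, dememorization = 2000, batches = 50,
                    iterations = 2000, seed = r)
    expect_lt(abs(res$p - p_enum), max(3 * res$se, 0.005))
  }
  # one-sided alternatives order sensibly for a heterozygote deficit
  rd <- hwe_test(gt, 1, alternative = "deficiency", batches = 20,
                 dememorization = 1000, iterations = 1000, seed = 2)
  re <- hwe_test(gt, 1, alternative = "excess", batches = 20,
                 dememorization = 1000, iterations = 1000, seed = 2)
  expect_lt(rd$p, 0.05)
  expect_gt(re$p, 0.9)
  expect_error(hwe_test(make_gt(rep(list(c(1L, 1L)), 6)), 1), "monomorphic")
})

test_that("HWE p-values are ~uniform under the null", {
  set.seed(7)
  ps <- replicate(40, {
    p <- runif(1, 0.2, 0.8)
    a <- sample(1:2, 60, TRUE, c(p, 1 - p))
    b <- sample(1:2, 60, TRUE, c(p, 1 - p))
    g <- genotype_table(cbind(pmin(a, b), pmax(a, b)), "L1")
    hwe_test(g, 1, dememorization = 500, batches = 20, iterations = 500)$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.75)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("exclusion probabilities match exhaustive trio enumeration", {
  # monomorphic: no exclusion power
  ex0 <- exclusion_probabilities(list(L1 = c(`1` = 1)))
  expect_equal(unname(ex0$cumulative), c(0, 0))
  for (p in list(c(0.5, 0.5), c(0.9, 0.1), c(0.5, 0.3, 0.2))) {
    names(p) <- seq_along(p)
    got <- exclusion_probabilities(list(L = p))$per_locus
    want <- brute_exclusion(as.numeric(p))
    expect_equal(got$PrEx1, unname(want["PrEx1"]), tolerance = 1e-10)
    expect_equal(got$PrEx2, unname(want["PrEx2"]), tolerance = 1e-10)
    expect_lte(got$PrEx1, got$PrEx2)
  }
  # cumulative combination is monotone and unchanged by monomorphic loci
  p2 <- c(`1` = 0.5, `2` = 0.5)
  one <- exclusion_probabilities(list(p2))$cumulative
  two <- exclusion_probabilities(list(p2, p2))$cumulative
  expect_true(all(two >= one))
  plus_mono <- exclusion_probabilities(list(p2, p2, c(`9` = 1)))$cumulative
  expect_equal(plus_mono, two)
})

test_that("cohort comparison ANOVA matches hand computation", {
  sA <- data.frame(locus = c("a", "b", "c"), Na = c(2, 4, 6))
  sB <- data.frame(locus = c("a", "b", "c"), Na = c(3, 5, 7))
  sC <- data.frame(locus = c("a", "b", "c"), Na = c(8, 10, 12))
  # hand one-way ANOVA: groups means 4, 5, 10; grand 19/3
  y <- c(2, 4, 6, 3, 5, 7, 8, 10, 12)
  gmeans <- c(4, 5, 10)
  ss_between <- 3 * sum((gmeans - mean(y))^2)
  ss_within <- sum((y - rep(gmeans, each = 3))^2)
  f_hand <- (ss_between / 2) / (ss_within / 6)
  got <- compare_locuswise_stats(list(A = sA, B = sB, C = sC),
                                 metrics = "Na")
  expect_equal(got$F, f_hand, tolerance = 1e-10)
  # identical cohorts: F = 0, p = 1
  same <- compare_locuswise_stats(list(A = sA, B = sA), metrics = "Na")
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # huge separation
  sBig <- data.frame(locus = c("a", "b", "c"), Na = c(2, 4, 6) + 100)
  far <- compare_locuswise_stats(list(A = sA, B = sBig), metrics = "Na")
  expect_lt(far$p, 1e-3)
})

test_that("cohort summaries expose cumulative exclusion over loci", {
  gt <- random_gt(n = 40, L = 5, k = 4, missing_rate = 0,
                  pop = rep(c("X", "Y"), 20))
  cs <- cohort_summary(gt)
  for (g in cs) {
    expect_gte(g$cumulative[["PrEx1"]],
               max(g$locus_table$PrEx1, na.rm = TRUE))
    expect_gte(g$cumulative[["PrEx2"]], g$cumulative[["PrEx1"]])
  }
})
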