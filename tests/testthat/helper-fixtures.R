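# Shared fixtures and independent oracles (brute force / enumeration),
# deliberately written against first principles rather than package internals.

# quick genotype_table from a matrix given as one row per sample
make_gt <- function(rows, loci = NULL, pop = NULL, samples = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(m) / 2))
  genotype_table(m, loci, samples = samples, pop = pop)
}

# random valid genotype table
random_gt <- function(n = 10, L = 4, k = 4, missing_rate = 0.1,
                      pop = NULL) {
  tab <- matrix(0L, n, 2L * L)
  for (l in seq_len(L)) {
    codes <- sort(sample(100:200, k))
    a <- sample(codes, n, replace = TRUE)
    b <- sample(codes, n, replace = TRUE)
    miss <- runif(n) < missing_rate
    a[miss] <- 0L; b[miss] <- 0L
    tab[, 2L * l - 1L] <- pmin(a, b); tab[, 2L * l] <- pmax(a, b)
  }
  if (!is.null(pop)) pop <- rep_len(pop, n)
  genotype_table(tab, paste0("L", seq_len(L)),
                 samples = sprintf("S%03d", seq_len(n)), pop = pop)
}

# --- exact HWE enumeration oracle (<= 3 alleles) ---------------------------
# enumerate all genotype-count tables with the observed allele counts;
# Levene conditional probability; two-sided p = sum of P(table) over tables
# no more probable than the observed one.
hwe_exact_enum <- function(geno) {
  # geno: n x 2 matrix of allele codes
  codes <- sort(unique(c(geno)))
  k <- length(codes)
  stopifnot(k <= 3)
  n <- nrow(geno)
  ac <- sapply(codes, function(cd) sum(geno == cd))  # allele counts
  cells <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  n_cells <- nrow(cells)
  log_prob <- function(cnt) {
    h <- sum(cnt[cells[, 1] != cells[, 2]])
    lfactorial(n) - sum(lfactorial(cnt)) + h * log(2) +
      sum(lfactorial(ac)) - lfactorial(2 * n)
  }
  obs_cnt <- integer(n_cells)
  for (i in seq_len(n)) {
    g <- sort(match(geno[i, ], codes))
    j <- which(cells[, 1] == g[1] & cells[, 2] == g[2])
    obs_cnt[j] <- obs_cnt[j] + 1L
  }
  lp_obs <- log_prob(obs_cnt)
  tables <- list()
  rec <- function(cnt, cell, rem) {
    if (cell > n_cells) {
      if (rem == 0) {
        acc <- sapply(codes, function(cd) {
          ci <- match(cd, codes)
          sum(cnt[cells[, 1] == ci]) + sum(cnt[cells[, 2] == ci])
        })
        if (all(acc == ac)) tables[[length(tables) + 1L]] <<- cnt
      }
      return(invisible())
    }
    for (v in 0:rem) rec(`[<-`(cnt, cell, v), cell + 1L, rem - v)
  }
  rec(integer(n_cells), 1L, n)
  lps <- vapply(tables, log_prob, numeric(1))
  tot <- sum(exp(lps))
  sum(exp(lps[lps <= lp_obs + 1e-9])) / tot
}

# --- brute-force exclusion probabilities -----------------------------------
# enumerate mother, father, offspring and random-male genotypes at HWE;
# PrEx1: random male shares no allele with the offspring (cannot be any
# parent, nothing else known); PrEx2: mother known, random male carries no
# allele consistent with the required paternal contribution.
enum_genotypes <- function(p) {
  k <- length(p)
  gs <- list(); probs <- numeric(0)
  for (i in 1:k) for (j in i:k) {
    gs[[length(gs) + 1L]] <- c(i, j)
    probs <- c(probs, if (i == j) p[i]^2 else 2 * p[i] * p[j])
  }
  list(g = gs, pr = probs)
}

brute_exclusion <- function(p) {
  eg <- enum_genotypes(p)
  k <- length(p)
  pr_off_given <- function(gm, gf) {
    # distribution of offspring genotype from parents gm x gf
    out <- matrix(0, k, k)
    for (a in gm) for (b in gf)
      out[min(a, b), max(a, b)] <- out[min(a, b), max(a, b)] + 0.25
    out
  }
  ex1 <- 0; ex2 <- 0
  for (m in seq_along(eg$g)) for (f in seq_along(eg$g)) {
    po <- pr_off_given(eg$g[[m]], eg$g[[f]])
    w_mf <- eg$pr[m] * eg$pr[f]
    for (a in 1:k) for (b in a:k) {
      if (po[a, b] == 0) next
      off <- c(a, b)
      # paternal-allele set given known mother
      pat <- integer(0)
      if (off[1] %in% eg$g[[m]]) pat <- c(pat, off[2])
      if (off[2] %in% eg$g[[m]]) pat <- c(pat, off[1])
      for (cand in seq_along(eg$g)) {
        w <- w_mf * po[a, b] * eg$pr[cand]
        if (!any(eg$g[[cand]] %in% off)) ex1 <- ex1 + w
        if (!any(eg$g[[cand]] %in% pat)) ex2 <- ex2 + w
      }
    }
  }
  c(PrEx1 = ex1, PrEx2 = ex2)
}

# --- Mendelian trio compatibility by gamete enumeration --------------------
trio_compatible <- function(off, mom, dad) {
  off <- sort(unname(as.integer(off)))
  for (am in unname(mom)) for (af in unname(dad)) {
    if (identical(sort(as.integer(c(am, af))), off)) return(TRUE)
  }
  FALSE
}

# small simulated dataset shared by several tests
small_sim <- function(seed = 1, sizes = c(30, 40, 25, 35), s = 0,
                      n_donors = 1, gens = 2) {
  cfg <- sim_config(n_generations = gens, selfing_rate = s,
                    n_donors = n_donors,
                    capsules = list(n = length(sizes), sizes = sizes,
                                    mothers = "random"),
                    rng_seed = seed)
  simulate_dataset(cfg)
}
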