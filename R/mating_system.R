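#' @name mating_system
#' @title Mixed-mating and correlated-paternity estimation
#' @description
#' Likelihood machinery for progeny arrays under the multilocus mixed-mating
#' model: each offspring is either a self of its known mother (probability
#' `1 - t`) or an outcross to a pollen pool at population allele frequencies
#' (probability `t`). Per-offspring, per-locus ingredients:
#' `A = P(genotype | selfing)`, `B = P(genotype | outcrossing)`, and the
#' distribution of the paternal allele given the maternal genotype, which the
#' sibling-pair correlated-paternity model reuses.
NULL

# progeny-array container ---------------------------------------------------

#' Bundle progeny arrays with genotypes
#'
#' @param mapping data frame `capsule_id, mother_id, offspring_id` (see
#'   [read_arrays_csv()]).
#' @param adults adult [genotype_table()] holding the mothers (and candidate
#'   fathers).
#' @param offspring offspring [genotype_table()].
#' @param min_offspring capsules below this size are dropped (the
#'   capsule-exclusion rule applied before mating/paternity analysis).
#' @return a `progeny_arrays` list: `mapping`, `capsules`, `adults`,
#'   `offspring`, `excluded`.
#' @export
progeny_arrays <- function(mapping, adults, offspring, min_offspring = 5L) {
  rep <- validate_dataset(adults, arrays = mapping, offspring = offspring,
                          min_offspring = min_offspring)
  keep_caps <- rep$capsules$capsule_id[rep$capsules$retained]
  mapping <- mapping[mapping$capsule_id %in% keep_caps, , drop = FALSE]
  structure(list(mapping = mapping,
                 capsules = rep$capsules[rep$capsules$retained, , drop = FALSE],
                 adults = adults, offspring = offspring,
                 excluded = rep$capsules[!rep$capsules$retained, , drop = FALSE]),
            class = "progeny_arrays")
}

#' @export
print.progeny_arrays <- function(x, ...) {
  cat("progeny_arrays:", nrow(x$capsules), "capsules,",
      nrow(x$mapping), "offspring retained")
  if (nrow(x$excluded)) cat(";", nrow(x$excluded), "capsules excluded")
  cat("\n")
  invisible(x)
}

# selfing probability of offspring genotype (a,b) given mother genotype
self_prob <- function(oa, ob, ma, mb) {
  g <- function(x) (x == ma) * 0.5 + (x == mb) * 0.5  # maternal gamete prob
  if (oa == ob) g(oa) * g(oa) else 2 * g(oa) * g(ob)
}

# per-offspring, per-locus likelihood pieces for one capsule:
# A (n x L selfing prob), B (n x L outcross prob), U (list over loci of
# n x k paternal-allele weight matrices with B = U %*% p)
mating_ingredients <- function(arr, capsule, freqs) {
  rows <- arr$mapping$capsule_id == capsule
  off_ids <- arr$mapping$offspring_id[rows]
  mom_id <- arr$mapping$mother_id[rows][1L]
  oidx <- match(off_ids, arr$offspring$samples)
  midx <- match(mom_id, arr$adults$samples)
  L <- length(arr$adults$loci)
  n <- length(off_ids)
  A <- matrix(1, n, L); B <- matrix(1, n, L)
  U <- vector("list", L)
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    codes <- as.integer(names(p))
    k <- length(p)
    m2 <- gt_locus(arr$adults, l)[midx, ]
    o2 <- gt_locus(arr$offspring, l)[oidx, , drop = FALSE]
    Ul <- matrix(0, n, max(k, 1L))
    if (m2[1L] == 0L || k == 0L) {  # mother untyped: locus uninformative
      U[[l]] <- Ul
      next
    }
    gm <- function(x) (x == m2[1L]) * 0.5 + (x == m2[2L]) * 0.5
    for (i in seq_len(n)) {
      if (o2[i, 1L] == 0L) next  # missing offspring call: skip locus
      oa <- o2[i, 1L]; ob <- o2[i, 2L]
      A[i, l] <- self_prob(oa, ob, m2[1L], m2[2L])
      ja <- match(oa, codes); jb <- match(ob, codes)
      if (oa == ob) {
        if (!is.na(ja)) Ul[i, ja] <- gm(oa)
      } else {
        if (!is.na(jb)) Ul[i, jb] <- Ul[i, jb] + gm(oa)
        if (!is.na(ja)) Ul[i, ja] <- Ul[i, ja] + gm(ob)
      }
      B[i, l] <- sum(Ul[i, ] * p)
    }
    U[[l]] <- Ul
  }
  As <- apply(A, 1L, prod)
  Bs <- apply(B, 1L, prod)
  dead <- As == 0 & Bs == 0  # incompatible with mother under both modes
  list(A = A, B = B, U = U, As = As, Bs = Bs, dead = dead,
       off_ids = off_ids, mother_id = mom_id, capsule = capsule)
}

prepare_mating <- function(arr, freqs) {
  caps <- arr$capsules$capsule_id
  if (!length(caps)) stop("no retained families")
  ings <- lapply(caps, function(cp) mating_ingredients(arr, cp, freqs))
  n_dead <- sum(vapply(ings, function(g) sum(g$dead), integer(1L)))
  if (n_dead > 0L)
    warning(n_dead, " offspring incompatible with mother excluded")
  ings
}

# EM for t on multilocus products As = prod_l A, Bs = prod_l B
em_outcrossing <- function(As, Bs, t0 = 0.9, tol = 1e-10, max_iter = 2000L,
                           check_monotone = FALSE) {
  t <- t0
  ll_prev <- -Inf
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    mix <- t * Bs + (1 - t) * As
    if (any(mix == 0))
      stop("offspring with zero likelihood under both mating modes")
    ll <- sum(log(mix))
    if (check_monotone && ll < ll_prev - 1e-8)
      stop("EM likelihood decreased")
    r <- t * Bs / mix
    t_new <- mean(r)
    conv <- abs(t_new - t) < tol
    t <- t_new
    ll_prev <- ll
    if (conv) return(list(t = t, loglik = ll, iters = it, converged = TRUE))
  }
  list(t = t, loglik = ll_prev, iters = max_iter, converged = FALSE)
}

# single-locus outcrossing rate MLE, reported unconstrained (can exceed 1
# when offspring look less selfed than the outcross expectation); maximized
# over the range keeping every per-offspring density positive
t_single_locus <- function(A, B) {
  d <- A - B
  upper <- 1.999
  neg <- d > 0  # density hits zero at t = A/(A-B)
  if (any(neg)) upper <- min(upper, min(A[neg] / d[neg]) - 1e-9)
  lower <- 0
  pos <- d < 0
  if (any(pos)) lower <- max(lower, max(-A[pos] / -d[pos], 0))
  if (upper <= lower) return(NA_real_)
  f <- function(t) sum(log((1 - t) * A + t * B))
  stats::optimize(f, c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

fit_mm_from_ing <- function(ings, L, t_start = 0.9, check_monotone = FALSE) {
  fam <- data.frame(capsule_id = vapply(ings, `[[`, "", "capsule"),
                    n = NA_integer_, t_m = NA_real_, t_s = NA_real_,
                    t_m_minus_t_s = NA_real_, converged = NA,
                    stringsAsFactors = FALSE)
  allA <- NULL; allB <- NULL
  A_all <- NULL; B_all <- NULL
  for (i in seq_along(ings)) {
    g <- ings[[i]]
    keep <- !g$dead
    fam$n[i] <- sum(keep)
    em <- em_outcrossing(g$As[keep], g$Bs[keep], t0 = t_start,
                         check_monotone = check_monotone)
    fam$t_m[i] <- em$t
    fam$converged[i] <- em$converged
    ts_l <- vapply(seq_len(L), function(l)
      t_single_locus(g$A[keep, l], g$B[keep, l]), numeric(1L))
    fam$t_s[i] <- mean(ts_l, na.rm = TRUE)
    fam$t_m_minus_t_s[i] <- fam$t_m[i] - fam$t_s[i]
    allA <- c(allA, g$As[keep]); allB <- c(allB, g$Bs[keep])
    A_all <- rbind(A_all, g$A[keep, , drop = FALSE])
    B_all <- rbind(B_all, g$B[keep, , drop = FALSE])
  }
  em_all <- em_outcrossing(allA, allB, t0 = t_start,
                           check_monotone = check_monotone)
  ts_all <- vapply(seq_len(L), function(l)
    t_single_locus(A_all[, l], B_all[, l]), numeric(1L))
  list(families = fam,
       pooled = list(t_m = em_all$t, t_s = mean(ts_all, na.rm = TRUE),
                     t_m_minus_t_s = em_all$t - mean(ts_all, na.rm = TRUE),
                     converged = em_all$converged, loglik = em_all$loglik))
}

#' Fit the multilocus mixed-mating model to progeny arrays
#'
#' Estimates the multilocus outcrossing rate `t_m` (EM with start 0.9,
#' constrained to `[0, 1]`) per family and pooled, the mean single-locus
#' rate `t_s` (per-locus maximum likelihood, reported unconstrained, so
#' values above 1 are possible), and biparental inbreeding `t_m - t_s`.
#' Pollen-pool allele frequencies default to the adult table (all candidate
#' fathers genotyped). Offspring with zero likelihood under both mating
#' modes (Mendelian-incompatible with their mother, e.g. from mistyping)
#' are excluded with a warning; genotyping error is not modelled inside the
#' likelihood.
#'
#' @param arr a [progeny_arrays()] object.
#' @param freqs optional pollen-pool allele-frequency list (default: adult
#'   frequencies).
#' @param t_start EM starting value (default 0.9).
#' @param check_monotone assert the EM likelihood never decreases.
#' @return a `mating_system_fit` list: `families` data frame (`capsule_id,
#'   n, t_m, t_s, t_m_minus_t_s, converged`), `pooled` (same quantities),
#'   `F_m` (fixation index over maternal genotypes),
#'   `n_excluded_offspring`.
#' @export
fit_mixed_mating <- function(arr, freqs = NULL, t_start = 0.9,
                             check_monotone = FALSE) {
  if (is.null(freqs)) freqs <- allele_frequencies(arr$adults)
  ings <- prepare_mating(arr, freqs)
  fit <- fit_mm_from_ing(ings, length(freqs), t_start, check_monotone)
  mothers <- unique(arr$mapping$mother_id)
  mom_sum <- locus_summary(gt_subset(arr$adults, mothers))
  ho <- mean(mom_sum$Ho, na.rm = TRUE); he <- mean(mom_sum$He, na.rm = TRUE)
  structure(c(fit, list(
      F_m = if (is.finite(he) && he > 0) 1 - ho / he else 0,
      n_excluded_offspring = sum(vapply(ings, function(g) sum(g$dead),
                                        integer(1L))))),
    class = "mating_system_fit")
}

#' @export
print.mating_system_fit <- function(x, ...) {
  print(x$families, row.names = FALSE, digits = 4)
  cat(sprintf("pooled: t_m = %.3f, t_s = %.3f, t_m - t_s = %.3f, F_m = %.3f\n",
              x$pooled$t_m, x$pooled$t_s, x$pooled$t_m_minus_t_s, x$F_m))
  invisible(x)
}

# per-family sib-pair data: full-sib / half-sib likelihood ratios per pair
# (multilocus and per locus) for the outcrossed offspring of one capsule
pair_ratios <- function(g, freqs, max_pairs = Inf) {
  L <- length(freqs)
  keep <- !g$dead
  # outcrossed = selfing impossible or dominated by the outcross likelihood
  out <- which(keep & (g$As == 0 | g$As < g$Bs))
  if (length(out) < 2L) return(NULL)
  pr <- utils::combn(out, 2L)
  if (ncol(pr) > max_pairs)
    pr <- pr[, sample.int(ncol(pr), max_pairs), drop = FALSE]
  np <- ncol(pr)
  logratio <- matrix(NA_real_, np, L)
  for (l in seq_len(L)) {
    p <- as.numeric(freqs[[l]])
    Ul <- g$U[[l]]
    B1 <- g$B[pr[1L, ], l]; B2 <- g$B[pr[2L, ], l]
    # P(shared-father pair) = (sum_a u1 u2 p_a + B1 B2) / 2
    s12 <- rowSums(Ul[pr[1L, ], , drop = FALSE] *
                   Ul[pr[2L, ], , drop = FALSE] *
                   rep(p, each = np))
    hs <- B1 * B2
    fs <- (s12 + hs) / 2
    logratio[, l] <- log(ifelse(hs > 0, fs / hs, 1))
  }
  list(multi = exp(rowSums(logratio)), by_locus = exp(logratio), n = np)
}

fit_cp_from_pairs <- function(pairs_list, L) {
  pairs_list <- pairs_list[!vapply(pairs_list, is.null, logical(1L))]
  n_pairs <- sum(vapply(pairs_list, `[[`, 0L, "n"))
  if (n_pairs == 0L) stop("no family with >= 2 outcrossed offspring")
  R_multi <- unlist(lapply(pairs_list, `[[`, "multi"))
  rhat <- function(R) {
    f <- function(r) sum(log(pmax((1 - r) + r * R, .Machine$double.xmin)))
    stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-9)$maximum
  }
  snap <- function(r) if (r > 1 - 1e-6) 1 else if (r < 1e-6) 0 else r
  r_pm <- snap(rhat(R_multi))
  r_ps_l <- vapply(seq_len(L), function(l) {
    R <- unlist(lapply(pairs_list, function(pp) pp$by_locus[, l]))
    if (all(abs(R - 1) < 1e-12)) NA_real_ else snap(rhat(R))
  }, numeric(1L))
  r_ps <- mean(r_ps_l, na.rm = TRUE)
  list(r_pm = r_pm, r_ps = r_ps, n_pairs = n_pairs)
}

#' Correlated paternity under the sibling-pair model
#'
#' Pairs of outcrossed siblings are full sibs (shared father) with
#' probability `r_p` and otherwise half sibs with independent fathers from
#' the pollen pool. `r_pm` maximizes the multilocus pair likelihood over all
#' within-family sib pairs; `r_ps` does the same per locus and averages;
#' `N_ep = 1 / r_pm` is the effective number of pollen donors per maternal
#' plant, and `r_ps - r_pm` indicates correlated paternity via related
#' fathers. `r_t` summarizes the among-locus correlation of the per-family
#' single-locus selfing signal (clamped to `[-1, 1]`).
#'
#' @inheritParams fit_mixed_mating
#' @param max_pairs optional cap on sib pairs per family (random subsample)
#'   to bound cost in very large families.
#' @param seed RNG seed (used only when subsampling pairs).
#' @return a `correlated_paternity_fit` list: `r_pm`, `r_ps`,
#'   `r_ps_minus_r_pm`, `N_ep`, `r_t`, `n_pairs`.
#' @export
correlated_paternity <- function(arr, freqs = NULL, max_pairs = Inf,
                                 seed = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(arr$adults)
  if (!is.null(seed)) set.seed(seed)
  ings <- prepare_mating(arr, freqs)
  L <- length(freqs)
  pairs_list <- lapply(ings, pair_ratios, freqs = freqs,
                       max_pairs = max_pairs)
  fit <- fit_cp_from_pairs(pairs_list, L)
  # r_t from the family x locus matrix of single-locus selfing estimates
  s_mat <- t(vapply(ings, function(g) {
    1 - pmin(pmax(vapply(seq_len(L), function(l)
      t_single_locus(g$A[!g$dead, l], g$B[!g$dead, l]), numeric(1L)), 0), 2)
  }, numeric(L)))
  r_t <- NA_real_
  if (nrow(s_mat) >= 2L) {
    cm <- suppressWarnings(stats::cor(s_mat, use = "pairwise.complete.obs"))
    vals <- cm[upper.tri(cm)]
    if (!all(is.na(vals)))
      r_t <- max(-1, min(1, mean(vals, na.rm = TRUE)))
  }
  structure(list(r_pm = fit$r_pm, r_ps = fit$r_ps,
                 r_ps_minus_r_pm = fit$r_ps - fit$r_pm,
                 N_ep = if (fit$r_pm > 0) 1 / fit$r_pm else Inf,
                 r_t = r_t, n_pairs = fit$n_pairs),
            class = "correlated_paternity_fit")
}

#' @export
print.correlated_paternity_fit <- function(x, ...) {
  cat(sprintf("r_pm = %.3f  r_ps = %.3f  N_ep = %.3f  (%d sib pairs)\n",
              x$r_pm, x$r_ps, x$N_ep, x$n_pairs))
  invisible(x)
}

#' Bootstrap standard errors by resampling maternal families
#'
#' Families (capsules) are resampled with replacement and the estimator is
#' refitted on each replicate; the SE is the standard deviation of replicate
#' estimates. The built-in estimators reuse precomputed per-family
#' likelihood ingredients, so a 1000-replicate bootstrap of eight large
#' families stays cheap. Replicates where the estimator fails are dropped
#' and counted.
#'
#' @param arr a [progeny_arrays()] object.
#' @param estimator `"mixed_mating"` (pooled t_m, t_s, t_m - t_s),
#'   `"correlated_paternity"` (r_pm, r_ps, N_ep), or a function
#'   `(progeny_arrays) -> named numeric vector` (generic, slower).
#' @param freqs optional pollen-pool allele frequencies.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param max_pairs per-family sib-pair cap (correlated paternity only).
#' @return list `se` (named vector), `estimates` (replicate matrix),
#'   `n_failed`.
#' @export
bootstrap_families <- function(arr, estimator = "mixed_mating", freqs = NULL,
                               n_boot = 1000L, seed = NULL,
                               max_pairs = Inf) {
  if (nrow(arr$capsules) < 2L) stop("need >= 2 families to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  n_fam <- nrow(arr$capsules)
  n_failed <- 0L
  reps <- vector("list", n_boot)
  if (is.function(estimator)) {
    caps <- arr$capsules$capsule_id
    for (b in seq_len(n_boot)) {
      pick <- sample(caps, n_fam, replace = TRUE)
      maps <- lapply(seq_along(pick), function(i) {
        mm <- arr$mapping[arr$mapping$capsule_id == pick[i], , drop = FALSE]
        mm$capsule_id <- sprintf("B%03d", i)
        mm
      })
      arr_b <- arr
      arr_b$mapping <- do.call(rbind, maps)
      arr_b$capsules <- data.frame(
        capsule_id = sprintf("B%03d", seq_along(pick)),
        mother_id = arr$capsules$mother_id[match(pick, caps)],
        n_offspring = arr$capsules$n_offspring[match(pick, caps)],
        retained = TRUE, stringsAsFactors = FALSE)
      est <- tryCatch(estimator(arr_b), error = function(e) NULL)
      if (is.null(est)) n_failed <- n_failed + 1L else reps[[b]] <- est
    }
  } else {
    estimator <- match.arg(estimator, c("mixed_mating",
                                        "correlated_paternity"))
    if (is.null(freqs)) freqs <- allele_frequencies(arr$adults)
    L <- length(freqs)
    ings <- prepare_mating(arr, freqs)
    pairs_list <- if (estimator == "correlated_paternity")
      lapply(ings, pair_ratios, freqs = freqs, max_pairs = max_pairs)
    for (b in seq_len(n_boot)) {
      pick <- sample.int(n_fam, n_fam, replace = TRUE)
      est <- tryCatch({
        if (estimator == "mixed_mating") {
          fit <- fit_mm_from_ing(ings[pick], L)
          c(t_m = fit$pooled$t_m, t_s = fit$pooled$t_s,
            t_m_minus_t_s = fit$pooled$t_m_minus_t_s)
        } else {
          fit <- fit_cp_from_pairs(pairs_list[pick], L)
          c(r_pm = fit$r_pm, r_ps = fit$r_ps,
            r_ps_minus_r_pm = fit$r_ps - fit$r_pm,
            N_ep = if (fit$r_pm > 0) 1 / fit$r_pm else NA_real_)
        }
      }, error = function(e) NULL)
      if (is.null(est)) n_failed <- n_failed + 1L else reps[[b]] <- est
    }
  }
  reps <- do.call(rbind, reps[!vapply(reps, is.null, logical(1L))])
  list(se = apply(reps, 2L, stats::sd), estimates = reps,
       n_failed = n_failed)
}
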