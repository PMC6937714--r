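#' Per-locus allele frequencies
#'
#' Frequencies are computed over fully typed calls only (missing calls drop
#' out of the denominator). Loci with zero typed calls in the group are
#' flagged with an empty frequency vector.
#'
#' @param gt a [genotype_table()].
#' @param group optional logical/integer/character selector of samples (a
#'   character vector is matched against sample ids, or against `gt$pop`
#'   labels when it matches none of the ids).
#' @return named list per locus: named numeric vector of frequencies (names =
#'   allele codes), with attribute `n_typed` = number of fully typed
#'   individuals.
#' @export
allele_frequencies <- function(gt, group = NULL) {
  idx <- resolve_group(gt, group)
  out <- vector("list", length(gt$loci))
  names(out) <- gt$loci
  for (l in seq_along(gt$loci)) {
    m <- gt_locus(gt, l)[idx, , drop = FALSE]
    typed <- m[, 1L] > 0L
    v <- c(m[typed, 1L], m[typed, 2L])
    if (!length(v)) {
      f <- numeric(0)
    } else {
      tb <- table(v)
      f <- stats::setNames(as.numeric(tb) / sum(tb), names(tb))
    }
    attr(f, "n_typed") <- sum(typed)
    out[[l]] <- f
  }
  out
}

resolve_group <- function(gt, group) {
  if (is.null(group)) return(seq_along(gt$samples))
  if (is.logical(group)) return(which(group))
  if (is.numeric(group)) return(as.integer(group))
  if (all(group %in% gt$samples)) return(match(group, gt$samples))
  if (!is.null(gt$pop) && all(group %in% gt$pop))
    return(which(gt$pop %in% group))
  stop("group selector matches neither sample ids nor pop labels")
}

#' Per-locus diversity summary
#'
#' Computes, per locus over a group of samples: observed allele count (Na),
#' effective allele count (Ne = 1 / sum p^2), Shannon's information index
#' (I = -sum p log p), observed heterozygosity (Ho), expected heterozygosity
#' (He = 1 - sum p^2, uncorrected GenAlEx convention, or Nei's unbiased
#' 2n/(2n-1) variant), inbreeding coefficient (Fis = 1 - Ho/He; reported as 0
#' and flagged for monomorphic loci), and per-locus paternity exclusion
#' probabilities.
#'
#' @inheritParams allele_frequencies
#' @param unbiased use Nei's small-sample correction for He.
#' @param hwe also run [hwe_test()] per polymorphic locus.
#' @param hwe_params list passed to [hwe_test()] (chain sizes, seed).
#' @return data frame with one row per locus: `locus, n, Na, Ne, I, Ho, He,
#'   Fis, PrEx1, PrEx2` (and `hwe_p` if requested), plus attribute
#'   `monomorphic` naming flagged loci.
#' @export
locus_summary <- function(gt, group = NULL, unbiased = FALSE,
                          hwe = FALSE, hwe_params = list()) {
  idx <- resolve_group(gt, group)
  freqs <- allele_frequencies(gt, group)
  L <- length(gt$loci)
  out <- data.frame(locus = gt$loci, n = NA_integer_, Na = NA_integer_,
                    Ne = NA_real_, I = NA_real_, Ho = NA_real_, He = NA_real_,
                    Fis = NA_real_, PrEx1 = NA_real_, PrEx2 = NA_real_,
                    stringsAsFactors = FALSE)
  mono <- character(0)
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    n_typed <- attr(p, "n_typed")
    out$n[l] <- n_typed
    if (!length(p)) next
    m <- gt_locus(gt, l)[idx, , drop = FALSE]
    typed <- m[, 1L] > 0L
    ho <- mean(m[typed, 1L] != m[typed, 2L])
    sp2 <- sum(p^2)
    he <- 1 - sp2
    if (unbiased && n_typed > 0)
      he <- he * 2 * n_typed / (2 * n_typed - 1)
    out$Na[l] <- length(p)
    out$Ne[l] <- 1 / sp2
    out$I[l] <- -sum(p * log(p))
    out$Ho[l] <- ho
    out$He[l] <- he
    if (he > 0) {
      out$Fis[l] <- 1 - ho / he
    } else {
      out$Fis[l] <- 0
      mono <- c(mono, gt$loci[l])
    }
    ex <- exclusion_probabilities(list(p))
    out$PrEx1[l] <- ex$per_locus$PrEx1[1L]
    out$PrEx2[l] <- ex$per_locus$PrEx2[1L]
  }
  if (hwe) {
    out$hwe_p <- NA_real_
    for (l in seq_len(L)) {
      if (!is.na(out$Na[l]) && out$Na[l] >= 2L && out$n[l] >= 5L) {
        res <- do.call(hwe_test, c(list(gt = gt, locus = gt$loci[l],
                                        group = group), hwe_params))
        out$hwe_p[l] <- res$p
      }
    }
  }
  attr(out, "monomorphic") <- mono
  out
}

#' Cohort/sub-population diversity summary
#'
#' Per-group [locus_summary()] plus across-locus means and cumulative
#' paternity exclusion probabilities (1 - prod(1 - per-locus value)), the
#' shape of a published diversity table.
#'
#' @inheritParams locus_summary
#' @param groups named list of sample selectors, or `NULL` to use `gt$pop`.
#' @return list of per-group results, each with `locus_table`, `means` and
#'   `cumulative` (PrEx1, PrEx2).
#' @export
cohort_summary <- function(gt, groups = NULL, unbiased = FALSE,
                           hwe = FALSE, hwe_params = list()) {
  if (is.null(groups)) {
    if (is.null(gt$pop)) stop("no groups given and gt has no pop labels")
    groups <- stats::setNames(as.list(unique(gt$pop)), unique(gt$pop))
  }
  out <- vector("list", length(groups))
  names(out) <- names(groups)
  for (g in seq_along(groups)) {
    tab <- locus_summary(gt, groups[[g]], unbiased = unbiased,
                         hwe = hwe, hwe_params = hwe_params)
    freqs <- allele_frequencies(gt, groups[[g]])
    ex <- exclusion_probabilities(freqs)
    num <- c("Na", "Ne", "I", "Ho", "He", "Fis")
    out[[g]] <- list(locus_table = tab,
                     n = length(resolve_group(gt, groups[[g]])),
                     means = colMeans(tab[, num], na.rm = TRUE),
                     cumulative = c(PrEx1 = ex$cumulative["PrEx1"][[1L]],
                                    PrEx2 = ex$cumulative["PrEx2"][[1L]]))
  }
  out
}

#' Markov-chain exact test of Hardy-Weinberg equilibrium
#'
#' Tests the null of random union of gametes conditionally on the observed
#' allele counts. The chain is a random-transposition walk on the arrangement
#' of the 2n gene copies into n individuals: proposals swap one allele
#' between two random individuals, which leaves the uniform distribution over
#' arrangements - exactly the conditional null - invariant, so every proposal
#' is accepted. The two-sided statistic is the conditional probability of the
#' genotype table (states with probability <= observed count toward p); the
#' one-sided alternatives use the heterozygote count. The Monte Carlo
#' standard error is estimated from batch means.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name or index.
#' @param group optional sample selector (see [allele_frequencies()]).
#' @param alternative `"two.sided"` (probability test), `"excess"` or
#'   `"deficiency"` of heterozygotes.
#' @param dememorization,batches,iterations Markov-chain parameters
#'   (defaults 10,000 each).
#' @param seed optional RNG seed.
#' @return list `p`, `se` (Monte Carlo SE), `h_obs` (observed heterozygote
#'   count), `alternative`.
#' @export
hwe_test <- function(gt, locus, group = NULL,
                     alternative = c("two.sided", "excess", "deficiency"),
                     dememorization = 10000L, batches = 10000L,
                     iterations = 10000L, seed = NULL) {
  alternative <- match.arg(alternative)
  idx <- resolve_group(gt, group)
  m <- gt_locus(gt, locus)[idx, , drop = FALSE]
  m <- m[m[, 1L] > 0L, , drop = FALSE]
  codes <- sort(unique(c(m)))
  if (length(codes) < 2L)
    stop("monomorphic locus: HWE test undefined")
  if (nrow(m) < 5L) stop("need >= 5 typed individuals")
  a <- match(m[, 1L], codes)
  b <- match(m[, 2L], codes)
  if (!is.null(seed)) set.seed(seed)
  alt <- match(alternative, c("two.sided", "excess", "deficiency"))
  res <- hwe_mc_chain(a, b, length(codes), as.integer(dememorization),
                      as.integer(batches), as.integer(iterations),
                      alt)
  list(p = res[1L], se = res[2L], h_obs = sum(a != b),
       alternative = alternative)
}

#' Paternity exclusion probabilities from allele frequencies
#'
#' Per-locus probabilities of excluding a random non-parent, in the
#' power-sum (Jamieson & Taylor) forms: `PrEx1` excludes the first parent
#' when neither parent is otherwise known; `PrEx2` excludes the second
#' (paternal) parent when the mother is known - always the larger of the
#' two. Loci combine as `1 - prod(1 - Q_l)`.
#'
#' @param freqs list of per-locus allele-frequency vectors (as from
#'   [allele_frequencies()]).
#' @return list `per_locus` (data frame `locus, PrEx1, PrEx2`) and
#'   `cumulative` (named vector over all loci).
#' @export
exclusion_probabilities <- function(freqs) {
  nm <- names(freqs)
  if (is.null(nm)) nm <- paste0("L", seq_along(freqs))
  per <- data.frame(locus = nm, PrEx1 = 0, PrEx2 = 0,
                    stringsAsFactors = FALSE)
  for (l in seq_along(freqs)) {
    p <- as.numeric(freqs[[l]])
    if (length(p) < 2L) next  # monomorphic: no exclusion power
    a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4); a5 <- sum(p^5)
    per$PrEx1[l] <- 1 - 4 * a2 + 2 * a2^2 + 4 * a3 - 3 * a4
    per$PrEx2[l] <- 1 - 2 * a2 + a3 + 2 * a4 - 3 * a5 - 2 * a2^2 +
      3 * a2 * a3
  }
  list(per_locus = per,
       cumulative = c(PrEx1 = 1 - prod(1 - per$PrEx1),
                      PrEx2 = 1 - prod(1 - per$PrEx2)))
}

#' Compare per-locus diversity statistics across cohorts
#'
#' One-way ANOVA per metric treating loci as replicates (the standard way a
#' diversity table's cohorts are compared), with a Tukey HSD pairwise table.
#'
#' @param summaries named list of [locus_summary()] data frames, one per
#'   cohort, rows paired by locus.
#' @param metrics which columns to compare.
#' @return data frame `metric, F, p` with attribute `tukey` (list of TukeyHSD
#'   results per metric).
#' @export
compare_locuswise_stats <- function(summaries,
                                    metrics = c("Na", "Ne", "I", "Ho",
                                                "He", "Fis")) {
  if (length(summaries) < 2L) stop("need >= 2 cohorts")
  L <- nrow(summaries[[1L]])
  if (L < 2L) stop("need >= 2 loci")
  cohort <- factor(rep(names(summaries), each = L))
  out <- data.frame(metric = metrics, F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  tukey <- vector("list", length(metrics)); names(tukey) <- metrics
  for (i in seq_along(metrics)) {
    y <- unlist(lapply(summaries, function(s) s[[metrics[i]]]),
                use.names = FALSE)
    if (stats::var(y, na.rm = TRUE) == 0) {
      out$F[i] <- 0; out$p[i] <- 1
      next
    }
    fit <- stats::aov(y ~ cohort)
    an <- summary(fit)[[1L]]
    out$F[i] <- an$`F value`[1L]
    out$p[i] <- an$`Pr(>F)`[1L]
    tukey[[i]] <- stats::TukeyHSD(fit)
  }
  attr(out, "tukey") <- tukey
  out
}
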