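#' Analysis of molecular variance (AMOVA) among sub-populations
#'
#' Partitions allele-level variance among and within groups from squared
#' Euclidean distances between allele-indicator vectors (each individual
#' contributes two pseudo-gamete rows per locus, so the total degrees of
#' freedom are `2N - 1`; sums of squares are invariant to the arbitrary
#' allele split). Fst is the among-group variance component over the total,
#' with negative components truncated to zero (with a warning). Significance
#' comes from permuting individuals (both gene copies together) among
#' groups. Hedrick's standardized G'st is computed from per-locus Hs/Ht as
#' `Gst / Gst_max`, `Gst_max = (k-1)(1-Hs) / (k-1+Hs)`.
#'
#' @param gt a [genotype_table()].
#' @param labels per-sample group labels; defaults to `gt$pop`.
#' @param n_perm number of label permutations (>= 999 recommended).
#' @param seed optional RNG seed for the permutations.
#' @return an `amova_result` list: `table` (SS, df, variance components,
#'   percentages), `Fst`, `p`, `Gst`, `Gpst`, `n_perm`.
#' @export
amova <- function(gt, labels = gt$pop, n_perm = 999L, seed = NULL) {
  if (is.null(labels)) stop("no group labels")
  labels <- as.character(labels)
  tb <- table(labels)
  if (length(tb) < 2L) stop("need >= 2 sub-populations")
  if (any(tb < 2L))
    stop("sub-population of size 1: ", names(tb)[tb < 2L][1L])
  X <- indicator_rows(gt)       # 2N x (total alleles), two rows per sample
  grp <- rep(labels, each = 2L)
  obs <- amova_components(X, grp)
  if (obs$sigma_a < 0) {
    warning("negative among-group variance component truncated to 0")
    obs$sigma_a <- 0
  }
  fst <- if (obs$sigma_a + obs$sigma_w > 0)
    obs$sigma_a / (obs$sigma_a + obs$sigma_w) else 0
  # permutation of individuals among groups
  p <- NA_real_
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(labels)
    count <- 0L
    for (b in seq_len(n_perm)) {
      lp <- labels[sample.int(n)]
      cc <- amova_components(X, rep(lp, each = 2L))
      sa <- max(cc$sigma_a, 0)
      f <- if (sa + cc$sigma_w > 0) sa / (sa + cc$sigma_w) else 0
      if (f >= fst) count <- count + 1L
    }
    p <- (count + 1L) / (n_perm + 1L)
  }
  gst <- gst_hedrick(gt, labels)
  tot <- obs$sigma_a + obs$sigma_w
  res <- list(table = data.frame(
                source = c("Among sub-populations",
                           "Within sub-populations", "Total"),
                SS = c(obs$ss_a, obs$ss_w, obs$ss_a + obs$ss_w),
                df = c(obs$df_a, obs$df_w, obs$df_a + obs$df_w),
                sigma2 = c(obs$sigma_a, obs$sigma_w, tot),
                pct = c(obs$sigma_a, obs$sigma_w, tot) / tot,
                stringsAsFactors = FALSE),
              Fst = fst, p = p, Gst = gst$Gst, Gpst = gst$Gpst,
              Hs = gst$Hs, Ht = gst$Ht, n_perm = n_perm)
  class(res) <- "amova_result"
  res
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (allele-level, df total =", x$table$df[3L], ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Fst = %.4f (p = %s, %d permutations)  G'st = %.4f\n",
              x$Fst, format.pval(x$p), x$n_perm, x$Gpst))
  invisible(x)
}

# one-hot allele rows: two rows per individual (one per gene copy), columns
# = all alleles of all loci; missing locus contributes zero rows
indicator_rows <- function(gt) {
  n <- length(gt$samples)
  blocks <- vector("list", length(gt$loci))
  for (l in seq_along(gt$loci)) {
    m <- gt_locus(gt, l)
    codes <- sort(unique(c(m[m > 0L])))
    k <- length(codes)
    Z <- matrix(0, 2L * n, k)
    i1 <- match(m[, 1L], codes)  # NA if missing
    i2 <- match(m[, 2L], codes)
    r1 <- seq(1L, 2L * n, by = 2L)
    ok1 <- !is.na(i1); ok2 <- !is.na(i2)
    Z[cbind(r1[ok1], i1[ok1])] <- 1
    Z[cbind(r1[ok2] + 1L, i2[ok2])] <- 1
    blocks[[l]] <- Z
  }
  do.call(cbind, blocks)
}

# one-level AMOVA components for unit rows X grouped by grp
amova_components <- function(X, grp) {
  grp <- as.factor(grp)
  N <- nrow(X)
  g <- nlevels(grp)
  mu <- colMeans(X)
  ss_tot <- sum(X * X) - N * sum(mu * mu)
  ss_w <- 0
  ng <- tabulate(grp)
  for (lev in seq_len(g)) {
    Xi <- X[as.integer(grp) == lev, , drop = FALSE]
    mi <- colMeans(Xi)
    ss_w <- ss_w + sum(Xi * Xi) - nrow(Xi) * sum(mi * mi)
  }
  ss_a <- ss_tot - ss_w
  df_a <- g - 1L
  df_w <- N - g
  ms_a <- ss_a / df_a
  ms_w <- ss_w / df_w
  n0 <- (N - sum(ng^2) / N) / df_a
  list(ss_a = ss_a, ss_w = ss_w, df_a = df_a, df_w = df_w,
       sigma_w = ms_w, sigma_a = (ms_a - ms_w) / n0)
}

# Nei Gst and Hedrick G'st from per-locus Hs (mean within-group He) and Ht
# (pooled-frequency He), averaged over loci
gst_hedrick <- function(gt, labels) {
  groups <- unique(labels)
  k <- length(groups)
  hs <- ht <- numeric(0)
  for (l in seq_along(gt$loci)) {
    m <- gt_locus(gt, l)
    typed <- m[, 1L] > 0L
    if (!any(typed)) next
    v <- c(m[typed, 1L], m[typed, 2L])
    pt <- table(v) / length(v)
    ht_l <- 1 - sum(pt^2)
    hs_l <- mean(vapply(groups, function(gp) {
      mg <- m[typed & labels == gp, , drop = FALSE]
      if (!nrow(mg)) return(NA_real_)
      vg <- c(mg)
      pg <- table(vg) / length(vg)
      1 - sum(pg^2)
    }, numeric(1L)), na.rm = TRUE)
    hs <- c(hs, hs_l); ht <- c(ht, ht_l)
  }
  Hs <- mean(hs); Ht <- mean(ht)
  gst <- if (Ht > 0) (Ht - Hs) / Ht else 0
  gst_max <- (k - 1) * (1 - Hs) / (k - 1 + Hs)
  list(Gst = gst, Gpst = if (gst_max > 0) gst / gst_max else 0,
       Hs = Hs, Ht = Ht)
}
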