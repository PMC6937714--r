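#' Pairwise kinship coefficients (Loiselle estimator)
#'
#' Multilocus kinship between all pairs of individuals, computed from
#' individual allele frequencies centred on the reference (sample) allele
#' frequencies, with the small-sample bias term `p(1-p)/(n-1)` added per
#' allele. Per-locus numerators and denominators are retained so the
#' multilocus coefficient is the ratio of sums over co-typed loci, and so
#' slopes can be jackknifed over loci. The estimator is centred: the mean
#' over all pairs is approximately zero when the reference frequencies come
#' from the sample itself. A Ritland (1996) variant is available.
#'
#' @param gt a [genotype_table()].
#' @param group optional sample selector (see [allele_frequencies()]).
#' @param freq_reference optional allele-frequency list to centre on
#'   (defaults to frequencies of the analysed group).
#' @param estimator `"loiselle"` (default) or `"ritland"`.
#' @return a `kinship_matrix` list: `F` (n x n symmetric, NA diagonal),
#'   `num`, `den` (n x n x L arrays of per-locus contributions), `samples`,
#'   `loci`.
#' @export
pairwise_kinship <- function(gt, group = NULL, freq_reference = NULL,
                             estimator = c("loiselle", "ritland")) {
  estimator <- match.arg(estimator)
  idx <- resolve_group(gt, group)
  n <- length(idx)
  L <- length(gt$loci)
  freqs <- if (is.null(freq_reference)) allele_frequencies(gt, group)
           else freq_reference
  num <- array(NA_real_, c(n, n, L))
  den <- array(NA_real_, c(n, n, L))
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    if (length(p) < 2L) next  # monomorphic or untyped: no information
    codes <- as.integer(names(p))
    m <- gt_locus(gt, l)[idx, , drop = FALSE]
    typed <- m[, 1L] > 0L
    n_l <- sum(typed)
    if (n_l < 2L) next
    # individual allele "dosage" frequencies x_ia in {0, .5, 1}
    X <- matrix(0, n, length(p))
    i1 <- match(m[, 1L], codes); i2 <- match(m[, 2L], codes)
    ok <- typed & !is.na(i1) & !is.na(i2)
    X[cbind(which(ok), i1[ok])] <- X[cbind(which(ok), i1[ok])] + 0.5
    X[cbind(which(ok), i2[ok])] <- X[cbind(which(ok), i2[ok])] + 0.5
    if (estimator == "loiselle") {
      Xc <- sweep(X, 2L, as.numeric(p))
      bias <- sum(p * (1 - p)) / (n_l - 1)
      Nl <- tcrossprod(Xc) + bias
      Dl <- sum(p * (1 - p))
    } else {  # Ritland 1996
      Xp <- sweep(X, 2L, as.numeric(p), `/`)
      Nl <- (tcrossprod(X, Xp) - 1) / (length(p) - 1)
      Dl <- 1
    }
    Nl[!ok, ] <- NA; Nl[, !ok] <- NA
    num[, , l] <- Nl
    den[, , l] <- ifelse(is.na(Nl), NA_real_, Dl)
  }
  sn <- rowSums(num, na.rm = TRUE, dims = 2L)
  sd_ <- rowSums(den, na.rm = TRUE, dims = 2L)
  Fm <- ifelse(sd_ > 0, sn / sd_, NA_real_)
  diag(Fm) <- NA_real_
  dimnames(Fm) <- list(gt$samples[idx], gt$samples[idx])
  structure(list(F = Fm, num = num, den = den,
                 samples = gt$samples[idx], loci = gt$loci,
                 estimator = estimator),
            class = "kinship_matrix")
}

#' Default distance-class edges for kinship correlograms
#'
#' 0-20 m in 5 m steps, 21-50 m in 10 m steps, 51-350 m in 50 m steps, and a
#' final 351-450 m class; classes are half-open intervals `(lo, hi]`.
#' @return numeric vector of class edges.
#' @export
default_class_edges <- function()
  c(0, 5, 10, 15, 20, 30, 40, 50, 100, 150, 200, 250, 300, 350, 450)

pair_upper <- function(n) which(upper.tri(matrix(0, n, n)))

#' Kinship correlogram with permutation envelopes
#'
#' Mean pairwise kinship per distance class with a null envelope obtained by
#' permuting spatial locations among individuals (the genotypes stay fixed;
#' only the genotype-location mapping is broken). A class is flagged
#' significant when its observed mean lies outside the 95% envelope.
#'
#' @param kin a [pairwise_kinship()] result.
#' @param coords data frame `id, x, y` covering the kinship samples.
#' @param class_edges distance-class edges, `(lo, hi]` intervals
#'   (default [default_class_edges()]).
#' @param n_perm number of location permutations.
#' @param seed optional RNG seed.
#' @return a `correlogram` list: per-class `d_mean` (realized mean pair
#'   distance), `F_mean`, `n_pairs`, `perm_lo`, `perm_hi`, `significant`;
#'   plus `edges`, `n_dropped` (pairs beyond the last edge).
#' @export
kinship_correlogram <- function(kin, coords, class_edges = default_class_edges(),
                                n_perm = 1000L, seed = NULL) {
  n <- length(kin$samples)
  ci <- match(kin$samples, coords$id)
  if (anyNA(ci)) stop("coordinates missing for sample ",
                      kin$samples[is.na(ci)][1L])
  x <- coords$x[ci]; y <- coords$y[ci]
  D <- as.matrix(stats::dist(cbind(x, y)))
  up <- pair_upper(n)
  dv <- D[up]
  fv <- kin$F[up]
  K <- length(class_edges) - 1L
  if (max(dv) > max(class_edges))
    message(sum(dv > max(class_edges)), " pairs beyond the last class edge dropped")
  cls <- cut_classes(dv, class_edges)
  keep <- !is.na(cls) & !is.na(fv)
  obs_mean <- class_means(fv[keep], cls[keep], K)
  d_mean <- class_means(dv[keep], cls[keep], K)
  n_pairs <- tabulate(cls[keep], nbins = K)
  perm_lo <- perm_hi <- rep(NA_real_, K)
  if (n_perm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    pm <- matrix(NA_real_, n_perm, K)
    iu <- row(D)[upper.tri(D)]; ju <- col(D)[upper.tri(D)]
    for (b in seq_len(n_perm)) {
      sig <- sample.int(n)
      dp <- D[cbind(sig[iu], sig[ju])]
      clp <- cut_classes(dp, class_edges)
      kp <- !is.na(clp) & !is.na(fv)
      pm[b, ] <- class_means(fv[kp], clp[kp], K)
    }
    perm_lo <- apply(pm, 2L, stats::quantile, 0.025, na.rm = TRUE)
    perm_hi <- apply(pm, 2L, stats::quantile, 0.975, na.rm = TRUE)
  }
  res <- list(edges = class_edges, d_mean = d_mean, F_mean = obs_mean,
              n_pairs = n_pairs, perm_lo = perm_lo, perm_hi = perm_hi,
              significant = !is.na(obs_mean) &
                (obs_mean < perm_lo | obs_mean > perm_hi),
              n_dropped = sum(dv > max(class_edges)),
              n_perm = n_perm)
  class(res) <- "correlogram"
  res
}

cut_classes <- function(d, edges) {
  cls <- findInterval(d, edges, left.open = TRUE)  # (lo, hi]
  cls[d <= edges[1L] | d > edges[length(edges)]] <- NA_integer_
  cls
}

class_means <- function(v, cls, K) {
  s <- rep(NA_real_, K)
  tb <- tabulate(cls, nbins = K)
  sm <- vapply(seq_len(K), function(k) sum(v[cls == k]), numeric(1L))
  s[tb > 0L] <- sm[tb > 0L] / tb[tb > 0L]
  s
}

#' @export
print.correlogram <- function(x, ...) {
  df <- data.frame(lo = x$edges[-length(x$edges)], hi = x$edges[-1L],
                   d_mean = round(x$d_mean, 1), F_mean = signif(x$F_mean, 3),
                   n_pairs = x$n_pairs, significant = x$significant)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Kinship-distance regression slope, jackknife CI and the Sp statistic
#'
#' Regresses pairwise kinship on the log of pairwise distance over all pairs
#' (not class means); the standard error of the slope is obtained by
#' delete-one-locus jackknifing of the multilocus kinship. The Sp statistic
#' is `-b_LF / (1 - F1)` where `F1` is the mean kinship of the first
#' distance class.
#'
#' @inheritParams kinship_correlogram
#' @return list `b_LF`, `se_jack`, `ci` (b +- 1.96 se), `Sp`, `F1`,
#'   `sp_undefined` flag (F1 = 1).
#' @export
slope_and_sp <- function(kin, coords, class_edges = default_class_edges()) {
  n <- length(kin$samples)
  ci <- match(kin$samples, coords$id)
  x <- coords$x[ci]; y <- coords$y[ci]
  D <- as.matrix(stats::dist(cbind(x, y)))
  up <- pair_upper(n)
  dv <- D[up]
  keep0 <- dv > 0
  slope_of <- function(Fv) {
    keep <- keep0 & !is.na(Fv)
    unname(stats::coef(stats::lm(Fv[keep] ~ log(dv[keep])))[2L])
  }
  b <- slope_of(kin$F[up])
  L <- dim(kin$num)[3L]
  informative <- which(vapply(seq_len(L), function(l)
    any(!is.na(kin$num[, , l])), logical(1L)))
  bj <- vapply(informative, function(l) {
    sn <- rowSums(kin$num[, , -l, drop = FALSE], na.rm = TRUE, dims = 2L)
    sd_ <- rowSums(kin$den[, , -l, drop = FALSE], na.rm = TRUE, dims = 2L)
    Fm <- ifelse(sd_ > 0, sn / sd_, NA_real_)
    slope_of(Fm[up])
  }, numeric(1L))
  Lj <- length(bj)
  se <- if (Lj >= 2L) sqrt((Lj - 1) / Lj * sum((bj - mean(bj))^2)) else NA_real_
  cls <- cut_classes(dv, class_edges)
  F1 <- mean(kin$F[up][which(cls == 1L)], na.rm = TRUE)
  sp_undef <- is.finite(F1) && F1 >= 1
  list(b_LF = b, se_jack = se,
       ci = b + c(-1.96, 1.96) * se,
       Sp = if (sp_undef) NA_real_ else -b / (1 - F1),
       F1 = F1, sp_undefined = sp_undef)
}

#' Cubic residual-curvature test of seed- versus pollen-limited dispersal
#'
#' Takes the correlogram class means, removes the linear trend of `F(d)` on
#' `ln(d)`, fits a third-degree polynomial in `ln(d)` to the residuals
#' `f(d) = a + b ln d + c2 (ln d)^2 + c3 (ln d)^3`, and evaluates the
#' curvature `k = 2 c2 + 6 c3 ln(d1)` at the mean distance of the first
#' class. `k > 0` (concave at short distance) indicates seed dispersal more
#' restricted than pollen dispersal (sigma_s << sigma_p); `k <= 0` indicates
#' pollen-restricted dispersal or no particular seed restriction.
#'
#' @param corr a [kinship_correlogram()] result.
#' @return a `dispersal_curvature` list: `coef` (a, b, c2, c3), `k`, `d1`,
#'   `verdict` in `{"seed_restricted", "pollen_restricted_or_neutral"}`.
#' @export
residual_curvature <- function(corr) {
  ok <- !is.na(corr$F_mean) & !is.na(corr$d_mean) & corr$d_mean > 0
  if (sum(ok) < 5L) stop("need >= 5 non-empty distance classes")
  ld <- log(corr$d_mean[ok])
  if (length(unique(round(ld, 12))) < 4L)
    stop("singular design: too few distinct ln(d) values")
  fmean <- corr$F_mean[ok]
  lin <- stats::lm(fmean ~ ld)
  resid <- stats::resid(lin)
  cub <- stats::lm(resid ~ ld + I(ld^2) + I(ld^3))
  cf <- unname(stats::coef(cub))
  d1 <- corr$d_mean[which(ok)[1L]]
  k <- 2 * cf[3L] + 6 * cf[4L] * log(d1)
  structure(list(coef = stats::setNames(cf, c("a", "b", "c2", "c3")),
                 k = k, d1 = d1,
                 verdict = if (k > 0) "seed_restricted"
                           else "pollen_restricted_or_neutral"),
            class = "dispersal_curvature")
}

#' @export
print.dispersal_curvature <- function(x, ...) {
  cat(sprintf("curvature k = %.4g at d1 = %.2f m -> %s\n",
              x$k, x$d1, x$verdict))
  invisible(x)
}

#' One-call fine-scale genetic structure analysis
#'
#' Kinship, correlogram, slope/Sp and curvature for one group of mapped
#' individuals.
#'
#' @inheritParams pairwise_kinship
#' @inheritParams kinship_correlogram
#' @return list `kinship`, `correlogram`, `slope` and `curvature`.
#' @export
fsgs_analysis <- function(gt, coords, group = NULL,
                          class_edges = default_class_edges(),
                          n_perm = 1000L, seed = NULL,
                          estimator = "loiselle") {
  kin <- pairwise_kinship(gt, group, estimator = estimator)
  corr <- kinship_correlogram(kin, coords, class_edges, n_perm, seed)
  sl <- slope_and_sp(kin, coords, class_edges)
  cur <- tryCatch(residual_curvature(corr), error = function(e) NULL)
  list(kinship = kin, correlogram = corr, slope = sl, curvature = cur)
}
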