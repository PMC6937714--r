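#' @name paternity
#' @title Likelihood-based paternity assignment with simulated confidence
#' @description
#' LOD scores compare the likelihood that a candidate sired an offspring
#' (given the known mother) with the likelihood that an arbitrary male from
#' the pollen pool did. A per-genotype mistyping model with a single error
#' rate applies to offspring and candidate genotypes: with probability `e` a
#' genotype is an unconstrained Hardy-Weinberg draw instead of the Mendelian
#' one. Confidence in an assignment comes from `delta`, the LOD gap between
#' the best and second-best candidate, calibrated by simulating mating
#' events under the study design (candidate number, sampling proportion,
#' typing rate, error rate).
NULL

# P(offspring genotype | mother genotype, father genotype), Mendelian,
# vectorised over candidate rows (fa, fb)
trans_prob_mf <- function(oa, ob, ma, mb, fa, fb) {
  gm <- function(x) (x == ma) * 0.5 + (x == mb) * 0.5
  gf <- function(x) (x == fa) * 0.5 + (x == fb) * 0.5
  if (oa == ob) gm(oa) * gf(oa) else gm(oa) * gf(ob) + gm(ob) * gf(oa)
}

# P(offspring genotype | mother genotype, father ~ pollen pool at freqs p)
trans_prob_mp <- function(oa, ob, ma, mb, p) {
  gm <- function(x) (x == ma) * 0.5 + (x == mb) * 0.5
  pa <- function(x) { i <- match(x, as.integer(names(p)))
                      if (is.na(i)) 0 else as.numeric(p[i]) }
  if (oa == ob) gm(oa) * pa(oa) else gm(oa) * pa(ob) + gm(ob) * pa(oa)
}

# P(genotype) under HWE at freqs p
hwe_prob <- function(oa, ob, p) {
  pa <- function(x) { i <- match(x, as.integer(names(p)))
                      if (is.na(i)) 0 else as.numeric(p[i]) }
  if (oa == ob) pa(oa)^2 else 2 * pa(oa) * pa(ob)
}

#' LOD score of candidate fathers for one offspring
#'
#' `LOD = sum_l ln[ P(g_o | g_m, g_f, e) / P(g_o | g_m, e) ]` over loci typed
#' in offspring, mother and candidate. With `error_rate = 0` a candidate
#' sharing no transmissible allele with the offspring at any locus scores
#' `-Inf` (Mendelian exclusion). When the mother is untyped at a locus, the
#' parent-offspring pair likelihood is used instead.
#'
#' @param offspring,mother single-row genotype matrices (`2L` allele
#'   columns) or sample ids resolved against `gt`.
#' @param candidates candidate [genotype_table()] (rows are scored).
#' @param freqs allele-frequency list of the pollen pool.
#' @param error_rate per-genotype mistyping rate in `[0, 1)`.
#' @param gt optional [genotype_table()] to resolve ids against.
#' @return numeric vector of LOD scores, one per candidate.
#' @export
lod_score <- function(offspring, mother, candidates, freqs, error_rate = 0,
                      gt = NULL) {
  row_of <- function(x) {
    if (is.character(x)) {
      if (is.null(gt)) stop("gt required to resolve sample ids")
      gt$tab[match(x, gt$samples), , drop = TRUE]
    } else as.integer(x)
  }
  og <- row_of(offspring); mg <- row_of(mother)
  ctab <- candidates$tab
  L <- length(freqs)
  e <- error_rate
  lod <- numeric(nrow(ctab))
  for (l in seq_len(L)) {
    p <- freqs[[l]]
    if (!length(p)) next
    cm <- c(2L * l - 1L, 2L * l)
    oa <- og[cm[1L]]; ob <- og[cm[2L]]
    if (oa == 0L) next                       # offspring untyped: skip locus
    ma <- mg[cm[1L]]; mb <- mg[cm[2L]]
    fa <- ctab[, cm[1L]]; fb <- ctab[, cm[2L]]
    typed_f <- fa > 0L
    if (ma > 0L) {
      tf <- trans_prob_mf(oa, ob, ma, mb, fa, fb)
      tp <- trans_prob_mp(oa, ob, ma, mb, p)
    } else {                                  # mother untyped: pair LOD
      pa <- function(x) { i <- match(x, as.integer(names(p)))
                          ifelse(is.na(i), 0, as.numeric(p[i])) }
      gf <- function(x) (x == fa) * 0.5 + (x == fb) * 0.5
      tf <- if (oa == ob) gf(oa) * pa(oa)
            else gf(oa) * pa(ob) + gf(ob) * pa(oa)
      tp <- hwe_prob(oa, ob, p)
    }
    hw <- hwe_prob(oa, ob, p)
    num <- e * hw + (1 - e) * (e * tp + (1 - e) * tf)
    den <- e * hw + (1 - e) * tp
    contrib <- ifelse(typed_f,
                      log(num) - log(den),
                      0)                      # candidate untyped: skip locus
    lod <- lod + as.numeric(contrib)
  }
  lod
}

#' Calibrate delta confidence thresholds by simulated mating events
#'
#' Simulates paternity-assignment experiments: for each event a mother and a
#' true father are drawn from a Hardy-Weinberg candidate pool, an offspring
#' is generated by Mendelian transmission with mistyping, each candidate is
#' independently included in the sampled candidate set with the stated
#' sampling proportion (the true father may therefore be absent), loci are
#' typed with the stated proportion, and LOD/delta are computed. The strict
#' (default 95%) and relaxed (default 80%) thresholds are the smallest delta
#' values such that the stated proportion of above-threshold top candidates
#' are the true father.
#'
#' @param freqs allele-frequency list defining the population.
#' @param settings list with `n_events`, `n_candidates`, `prop_sampled`,
#'   `prop_loci_typed`, `error_rate`, and optional `levels` (default
#'   `c(strict = 0.95, relaxed = 0.80)`).
#' @param seed RNG seed.
#' @return a `confidence_thresholds` list: `delta_strict`, `delta_relaxed`,
#'   `settings`, `events` (delta and correctness per simulated event),
#'   `assignment_rate` (share of events assigned at each level).
#' @export
calibrate_confidence <- function(freqs, settings, seed = NULL) {
  need <- c("n_events", "n_candidates", "prop_sampled", "prop_loci_typed",
            "error_rate")
  if (!all(need %in% names(settings)))
    stop("settings must contain: ", paste(need, collapse = ", "))
  levels <- settings$levels
  if (is.null(levels)) levels <- c(strict = 0.95, relaxed = 0.80)
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  nc <- settings$n_candidates
  # one simulated candidate pool per calibration
  pool <- matrix(0L, nc, 2L * L)
  for (l in seq_len(L)) pool[, c(2L * l - 1L, 2L * l)] <-
    rhwe_genotypes(nc, freqs[[l]])
  pool_gt <- genotype_table(pool, names(freqs),
                            samples = sprintf("SIM%04d", seq_len(nc)))
  mistype <- function(g, l) {
    # with prob e replace the genotype by an HWE draw
    if (stats::runif(1L) < settings$error_rate)
      rhwe_genotypes(1L, freqs[[l]])[1L, ] else g
  }
  delta <- numeric(settings$n_events)
  correct <- logical(settings$n_events)
  has_top <- logical(settings$n_events)
  for (ev in seq_len(settings$n_events)) {
    mi <- sample.int(nc, 1L)
    fi <- sample.int(nc - 1L, 1L); if (fi >= mi) fi <- fi + 1L
    og <- integer(2L * L)
    for (l in seq_len(L)) {
      cm <- c(2L * l - 1L, 2L * l)
      if (stats::runif(1L) > settings$prop_loci_typed) next  # untyped locus
      a <- pool[mi, cm][1L + (stats::runif(1L) < 0.5)]
      b <- pool[fi, cm][1L + (stats::runif(1L) < 0.5)]
      g <- mistype(c(min(a, b), max(a, b)), l)
      og[cm] <- c(min(g), max(g))
    }
    inset <- which(stats::runif(nc) < settings$prop_sampled)
    inset <- setdiff(inset, mi)
    if (!length(inset)) { has_top[ev] <- FALSE; next }
    lods <- lod_score(og, pool[mi, ], gt_subset(pool_gt, inset), freqs,
                      settings$error_rate)
    fin <- is.finite(lods)
    if (!any(fin)) { has_top[ev] <- FALSE; next }
    ord <- order(lods, decreasing = TRUE)
    best <- ord[1L]
    has_top[ev] <- TRUE
    delta[ev] <- if (sum(fin) >= 2L) lods[best] - lods[ord[2L]]
                 else lods[best]
    correct[ev] <- inset[best] == fi
  }
  pick_threshold <- function(gamma) {
    d <- delta[has_top]; cc <- correct[has_top]
    o <- order(d, decreasing = TRUE)
    prec <- cumsum(cc[o]) / seq_along(o)
    ok <- which(prec >= gamma)
    if (!length(ok)) {
      warning("confidence level ", gamma, " unattainable; threshold = Inf")
      return(Inf)
    }
    d[o][max(ok)]
  }
  thr <- vapply(levels, pick_threshold, numeric(1L))
  res <- list(delta_strict = thr[[1L]], delta_relaxed = thr[[2L]],
              settings = settings,
              events = data.frame(delta = delta, correct = correct,
                                  has_top = has_top),
              assignment_rate = c(
                strict = mean(has_top & delta >= thr[[1L]]),
                relaxed = mean(has_top & delta >= thr[[2L]])))
  class(res) <- "confidence_thresholds"
  res
}

#' @export
print.confidence_thresholds <- function(x, ...) {
  cat(sprintf("delta thresholds: strict %.3f, relaxed %.3f (from %d events)\n",
              x$delta_strict, x$delta_relaxed, x$settings$n_events))
  cat(sprintf("assignment rate: %.1f%% strict, %.1f%% relaxed\n",
              100 * x$assignment_rate[["strict"]],
              100 * x$assignment_rate[["relaxed"]]))
  invisible(x)
}

#' Assign paternity to progeny arrays by LOD and delta tiers
#'
#' Ranks every candidate father by LOD for each offspring, computes delta
#' (gap to the second-best finite LOD) and assigns a confidence tier by the
#' calibrated thresholds. Per capsule the modal strict-tier father and the
#' proportion of offspring assigned to it are reported, with the
#' mother-father distance when coordinates are given. Candidates equal to
#' the mother are excluded unless selfing is allowed; a pure highest-LOD
#' mode (no delta tiers) is available.
#'
#' @param arr a [progeny_arrays()] object (candidates = `arr$adults`).
#' @param thresholds a [calibrate_confidence()] result (or list with
#'   `delta_strict`, `delta_relaxed`).
#' @param freqs optional allele-frequency list (default adult frequencies).
#' @param error_rate per-genotype mistyping rate.
#' @param coords optional coordinates (`id, x, y`) for dispersal distances.
#' @param allow_selfing include the mother among candidates.
#' @param criterion `"delta"` (tiered, default) or `"lod"` (best finite LOD
#'   wins, all assignments strict).
#' @return a `paternity_result` list: `assignments` (per offspring: best
#'   father, LOD, delta, confidence, distance), `capsules` (modal father,
#'   n assigned, proportion, distance), `n_assigned` by tier.
#' @export
assign_paternity <- function(arr, thresholds, freqs = NULL, error_rate = 0,
                             coords = NULL, allow_selfing = FALSE,
                             criterion = c("delta", "lod")) {
  criterion <- match.arg(criterion)
  if (is.null(freqs)) freqs <- allele_frequencies(arr$adults)
  cand <- arr$adults
  n_off <- nrow(arr$mapping)
  out <- data.frame(offspring_id = arr$mapping$offspring_id,
                    capsule_id = arr$mapping$capsule_id,
                    mother_id = arr$mapping$mother_id,
                    father_id = NA_character_, LOD = NA_real_,
                    delta = NA_real_, confidence = "unassigned",
                    distance_m = NA_real_, stringsAsFactors = FALSE)
  oidx <- match(arr$mapping$offspring_id, arr$offspring$samples)
  midx <- match(arr$mapping$mother_id, cand$samples)
  for (i in seq_len(n_off)) {
    og <- arr$offspring$tab[oidx[i], ]
    if (og[1L] == 0L && all(og == 0L)) next
    mg <- cand$tab[midx[i], ]
    lods <- lod_score(og, mg, cand, freqs, error_rate)
    drop <- if (allow_selfing) integer(0) else midx[i]
    if (length(drop)) lods[drop] <- -Inf
    if (identical(arr$mapping$offspring_id[i], cand$samples[midx[i]]))
      stop("offspring cannot be its own candidate")
    fin <- which(is.finite(lods))
    if (!length(fin)) next
    ord <- fin[order(lods[fin], decreasing = TRUE)]
    best <- ord[1L]
    dlt <- if (length(ord) >= 2L) lods[best] - lods[ord[2L]] else lods[best]
    out$father_id[i] <- cand$samples[best]
    out$LOD[i] <- lods[best]
    out$delta[i] <- dlt
    out$confidence[i] <- if (criterion == "lod") "strict95"
      else if (dlt >= thresholds$delta_strict) "strict95"
      else if (dlt >= thresholds$delta_relaxed) "relaxed80"
      else "unassigned"
  }
  if (!is.null(coords)) {
    fi <- match(out$father_id, coords$id)
    mi <- match(out$mother_id, coords$id)
    ok <- !is.na(fi) & out$confidence != "unassigned"
    out$distance_m[ok] <- sqrt((coords$x[fi[ok]] - coords$x[mi[ok]])^2 +
                               (coords$y[fi[ok]] - coords$y[mi[ok]])^2)
  }
  caps <- unique(out$capsule_id)
  cap_df <- data.frame(capsule_id = caps, mother_id = NA_character_,
                       n_offspring = NA_integer_, father_id = NA_character_,
                       n_assigned = 0L, assigned_proportion = NA_real_,
                       distance_m = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(caps)) {
    rows <- out[out$capsule_id == caps[j], , drop = FALSE]
    cap_df$mother_id[j] <- rows$mother_id[1L]
    cap_df$n_offspring[j] <- nrow(rows)
    strict <- rows[rows$confidence == "strict95" & !is.na(rows$father_id), ]
    if (nrow(strict)) {
      tb <- sort(table(strict$father_id), decreasing = TRUE)
      cap_df$father_id[j] <- names(tb)[1L]
      cap_df$n_assigned[j] <- as.integer(tb[1L])
      cap_df$assigned_proportion[j] <-
        100 * tb[[1L]] / cap_df$n_offspring[j]
      if (!is.null(coords)) {
        fi <- match(cap_df$father_id[j], coords$id)
        mi <- match(cap_df$mother_id[j], coords$id)
        cap_df$distance_m[j] <- sqrt((coords$x[fi] - coords$x[mi])^2 +
                                     (coords$y[fi] - coords$y[mi])^2)
      }
    }
  }
  res <- list(assignments = out, capsules = cap_df,
              n_assigned = c(strict = sum(out$confidence == "strict95"),
                             relaxed = sum(out$confidence %in%
                                             c("strict95", "relaxed80")),
                             total = n_off))
  class(res) <- "paternity_result"
  res
}

#' @export
print.paternity_result <- function(x, ...) {
  n <- x$n_assigned
  cat(sprintf("paternity: %d/%d (%.1f%%) strict, %d/%d (%.1f%%) relaxed\n",
              n[["strict"]], n[["total"]], 100 * n[["strict"]] / n[["total"]],
              n[["relaxed"]], n[["total"]], 100 * n[["relaxed"]] / n[["total"]]))
  print(x$capsules, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pollen-dispersal distance summary over assigned capsules
#'
#' Euclidean mother-father distances of capsules with an assigned father:
#' arithmetic mean, sample SD (n - 1), min, max. With a single assignment
#' the SD is undefined (`NA`) and flagged.
#'
#' @param assignments a [assign_paternity()] result (or a data frame with a
#'   `distance_m` column, e.g. its `capsules` table).
#' @return list `n`, `mean`, `sd`, `min`, `max`, `distances`,
#'   `sd_undefined`.
#' @export
dispersal_summary <- function(assignments) {
  d <- if (inherits(assignments, "paternity_result"))
    assignments$capsules$distance_m else assignments$distance_m
  d <- d[!is.na(d)]
  if (!length(d))
    return(list(n = 0L, mean = NA_real_, sd = NA_real_, min = NA_real_,
                max = NA_real_, distances = numeric(0), sd_undefined = TRUE))
  list(n = length(d), mean = mean(d),
       sd = if (length(d) >= 2L) stats::sd(d) else NA_real_,
       min = min(d), max = max(d), distances = d,
       sd_undefined = length(d) < 2L)
}
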