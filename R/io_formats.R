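#' Diploid codominant genotype table
#'
#' Container for individuals x loci diploid SSR calls. Allele codes are
#' positive integers (fragment sizes); 0 marks a missing allele. A call is
#' either fully typed (both alleles > 0) or fully missing (both 0); allele
#' pairs are stored sorted ascending so that phase never matters downstream.
#'
#' @param tab integer matrix, one row per sample and two columns per locus.
#' @param loci character vector of locus names (unique), length `ncol(tab)/2`.
#' @param samples sample ids (unique); defaults to rownames of `tab`.
#' @param pop optional per-sample population/cohort label.
#' @return An object of class `genotype_table` with fields `tab`, `loci`,
#'   `samples`, `pop`.
#' @export
genotype_table <- function(tab, loci, samples = rownames(tab), pop = NULL) {
  tab <- as.matrix(tab)
  if (ncol(tab) %% 2L != 0L)
    stop("genotype table must have two allele columns per locus")
  if (length(loci) != ncol(tab) / 2L)
    stop("length(loci) must equal ncol(tab)/2")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(tab)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample id: ",
                                   samples[duplicated(samples)][1L])
  storage.mode(tab) <- "integer"
  if (anyNA(tab) || any(tab < 0L))
    stop("allele codes must be non-negative integers (0 = missing)")
  # enforce fully-typed-or-fully-missing and sort pairs ascending
  for (l in seq_along(loci)) {
    a <- tab[, 2L * l - 1L]; b <- tab[, 2L * l]
    half <- xor(a == 0L, b == 0L)
    if (any(half))
      stop("half-missing call at locus '", loci[l], "', sample '",
           samples[which(half)[1L]], "': a call must be fully typed or fully missing")
    lo <- pmin(a, b); hi <- pmax(a, b)
    tab[, 2L * l - 1L] <- lo; tab[, 2L * l] <- hi
  }
  dimnames(tab) <- list(samples, paste0(rep(loci, each = 2L), c("_1", "_2")))
  if (!is.null(pop)) {
    if (length(pop) != nrow(tab)) stop("pop must have one label per sample")
    pop <- as.character(pop)
  }
  structure(list(tab = tab, loci = as.character(loci),
                 samples = samples, pop = pop),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$samples), "samples,",
      length(x$loci), "loci\n")
  if (!is.null(x$pop)) {
    tb <- table(x$pop)
    cat("groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$samples), length(x$loci))

# two-column allele matrix for one locus
gt_locus <- function(gt, locus) {
  l <- if (is.character(locus)) match(locus, gt$loci) else locus
  if (is.na(l) || l < 1L || l > length(gt$loci)) stop("unknown locus: ", locus)
  gt$tab[, c(2L * l - 1L, 2L * l), drop = FALSE]
}

#' Subset a genotype table by sample
#'
#' @param gt a [genotype_table()].
#' @param i sample ids (character) or indices.
#' @return a `genotype_table` with the selected samples, input order preserved.
#' @export
gt_subset <- function(gt, i) {
  if (is.character(i)) {
    idx <- match(i, gt$samples)
    if (anyNA(idx)) stop("unknown sample id: ", i[is.na(idx)][1L])
  } else idx <- i
  genotype_table(gt$tab[idx, , drop = FALSE], gt$loci,
                 samples = gt$samples[idx],
                 pop = if (!is.null(gt$pop)) gt$pop[idx])
}

#' Read a GenAlEx-style genotype CSV
#'
#' Expected layout: a header row naming columns `id,pop,<locus>_1,<locus>_2,...`
#' (two columns per locus; any pair of suffixes is accepted as long as the
#' stripped names agree within a pair), then one row per sample. `0` encodes a
#' missing allele; lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [genotype_table()].
#' @export
read_genotype_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("malformed header: need id, pop and >=1 locus (2 columns)")
  nm <- names(df)
  if (!identical(tolower(nm[1:2]), c("id", "pop")))
    stop("malformed header: first two columns must be 'id' and 'pop'")
  if ((ncol(df) - 2L) %% 2L != 0L)
    stop("malformed header: odd number of allele columns")
  acols <- nm[-(1:2)]
  strip <- sub("[._][12ab]$", "", acols)
  l1 <- strip[seq(1L, length(strip), by = 2L)]
  l2 <- strip[seq(2L, length(strip), by = 2L)]
  if (!identical(l1, l2))
    stop("malformed header: allele column pairs do not match by locus name")
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  bad <- which(!vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]; is.numeric(v) && all(v == floor(v))
  }, logical(1L)))
  if (length(bad)) {
    j <- bad[1L]
    v <- suppressWarnings(as.numeric(mat[, j]))
    row <- which(is.na(v) | v != floor(v))[1L]
    stop("non-integer allele at row ", row, ", column '", acols[j], "'")
  }
  genotype_table(mat, loci = l1, samples = as.character(df[[1L]]),
                 pop = as.character(df[[2L]]))
}

#' Write a genotype table as GenAlEx-style CSV
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @export
write_genotype_csv <- function(gt, path) {
  df <- data.frame(id = gt$samples,
                   pop = if (is.null(gt$pop)) "1" else gt$pop,
                   gt$tab, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write mapped-individual coordinate files
#'
#' `coords.csv` columns: `id,x,y,subpop,cohort`; coordinates are planar metres
#' (Euclidean distances throughout), `cohort` is `adult` or `seedling`.
#'
#' @param path file path.
#' @param subpops optional declared set of sub-population labels to validate
#'   against.
#' @return data frame with columns `id, x, y, subpop, cohort`.
#' @export
read_coords_csv <- function(path, subpops = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "subpop", "cohort")
  if (!all(need %in% names(df)))
    stop("coords file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate sample id: ",
                                 df$id[duplicated(df$id)][1L])
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop("coordinates must be finite")
  if (!is.null(subpops) && !all(df$subpop %in% subpops))
    stop("subpop label outside declared set: ",
         setdiff(df$subpop, subpops)[1L])
  df
}

#' @rdname read_coords_csv
#' @param coords data frame as returned by [read_coords_csv()].
#' @export
write_coords_csv <- function(coords, path) {
  utils::write.csv(coords[, c("id", "x", "y", "subpop", "cohort")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write progeny-array mapping files
#'
#' `arrays.csv` columns: `capsule_id,mother_id,offspring_id`, one row per
#' offspring; every offspring of a capsule shares the capsule's known mother.
#'
#' @param path file path.
#' @return data frame with columns `capsule_id, mother_id, offspring_id`.
#' @export
read_arrays_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("capsule_id", "mother_id", "offspring_id")
  if (!all(need %in% names(df)))
    stop("arrays file must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  for (j in need) df[[j]] <- as.character(df[[j]])
  mom <- unique(df[, c("capsule_id", "mother_id")])
  if (anyDuplicated(mom$capsule_id))
    stop("capsule with more than one mother: ",
         mom$capsule_id[duplicated(mom$capsule_id)][1L])
  df
}

#' @rdname read_arrays_csv
#' @param arrays data frame as returned by [read_arrays_csv()].
#' @export
write_arrays_csv <- function(arrays, path) {
  utils::write.csv(arrays[, c("capsule_id", "mother_id", "offspring_id")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# TRUE where offspring shares >=1 allele with mother at a locus; NA where
# either call is missing. Vectorised over offspring rows.
mendel_compatible_locus <- function(off2, mom2) {
  miss <- off2[, 1L] == 0L | mom2[1L] == 0L
  ok <- off2[, 1L] == mom2[1L] | off2[, 1L] == mom2[2L] |
        off2[, 2L] == mom2[1L] | off2[, 2L] == mom2[2L]
  ok[miss] <- NA
  ok
}

#' Validate a mapped-genotype dataset before analysis
#'
#' Cross-checks genotype tables, coordinates and progeny arrays: resolves ids,
#' flags capsules below the minimum retained family size (these are excluded
#' from mating-system and paternity stages but kept in cohort diversity
#' summaries), and flags mother-offspring Mendelian incompatibilities
#' (offspring sharing no maternal allele at a fully typed locus).
#'
#' @param adults adult [genotype_table()].
#' @param coords optional coordinates data frame (see [read_coords_csv()]).
#' @param arrays optional progeny-array mapping (see [read_arrays_csv()]).
#' @param offspring optional offspring [genotype_table()] (required for the
#'   Mendelian check when `arrays` is given).
#' @param min_offspring minimum family size retained for mating/paternity
#'   analyses (default 5).
#' @param error_rate declared genotyping error rate; when > 0, Mendelian
#'   incompatibilities are reported but not treated as fatal.
#' @return a `validation_report` list: `capsules` (per-capsule size and
#'   retained flag), `n_retained`, `n_excluded`, `n_offspring_retained`,
#'   `incompatibilities` (offspring x locus), `errors` free-form notes.
#' @export
validate_dataset <- function(adults, coords = NULL, arrays = NULL,
                             offspring = NULL, min_offspring = 5L,
                             error_rate = 0) {
  rep <- list(capsules = NULL, n_retained = 0L, n_excluded = 0L,
              n_offspring_retained = 0L,
              incompatibilities = data.frame(offspring_id = character(),
                                             locus = character()),
              notes = character())
  if (!is.null(coords)) {
    extra <- setdiff(adults$samples, coords$id)
    if (length(extra))
      stop("adult sample missing from coordinates: ", extra[1L])
  }
  if (!is.null(arrays)) {
    bad <- setdiff(unique(arrays$mother_id), adults$samples)
    if (length(bad)) stop("unknown mother id: ", bad[1L])
    # order-independent capsule summary
    sizes <- table(arrays$capsule_id)
    caps <- data.frame(capsule_id = names(sizes),
                       mother_id = arrays$mother_id[match(names(sizes),
                                                          arrays$capsule_id)],
                       n_offspring = as.integer(sizes),
                       stringsAsFactors = FALSE)
    caps <- caps[order(caps$capsule_id), , drop = FALSE]
    caps$retained <- caps$n_offspring >= min_offspring
    rownames(caps) <- NULL
    rep$capsules <- caps
    rep$n_retained <- sum(caps$retained)
    rep$n_excluded <- sum(!caps$retained)
    rep$n_offspring_retained <-
      sum(caps$n_offspring[caps$retained])
    if (!is.null(offspring)) {
      miss <- setdiff(arrays$offspring_id, offspring$samples)
      if (length(miss)) stop("offspring id not genotyped: ", miss[1L])
      inc <- vector("list", length(adults$loci))
      for (l in seq_along(adults$loci)) {
        off2 <- gt_locus(offspring, l)[match(arrays$offspring_id,
                                             offspring$samples), , drop = FALSE]
        momtab <- gt_locus(adults, l)
        momidx <- match(arrays$mother_id, adults$samples)
        ok <- off2[, 1L] == momtab[momidx, 1L] |
              off2[, 1L] == momtab[momidx, 2L] |
              off2[, 2L] == momtab[momidx, 1L] |
              off2[, 2L] == momtab[momidx, 2L]
        miss <- off2[, 1L] == 0L | momtab[momidx, 1L] == 0L
        bad <- which(!ok & !miss)
        if (length(bad))
          inc[[l]] <- data.frame(offspring_id = arrays$offspring_id[bad],
                                 locus = adults$loci[l],
                                 stringsAsFactors = FALSE)
      }
      inc <- do.call(rbind, inc[!vapply(inc, is.null, logical(1L))])
      if (!is.null(inc)) {
        inc <- inc[order(inc$offspring_id, inc$locus), , drop = FALSE]
        rownames(inc) <- NULL
        rep$incompatibilities <- inc
        if (error_rate == 0 && nrow(inc))
          rep$notes <- c(rep$notes, sprintf(
            "%d mother-offspring incompatibilities at error rate 0", nrow(inc)))
      }
    }
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report\n")
  if (!is.null(x$capsules)) {
    cat("  capsules retained:", x$n_retained, " excluded:", x$n_excluded, "\n")
    cat("  offspring retained for mating/paternity:",
        x$n_offspring_retained, "\n")
  }
  cat("  Mendelian incompatibilities:", nrow(x$incompatibilities), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
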