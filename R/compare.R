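#' Bin interaction sites into 1 Mb bins
#'
#' Counts intrachromosomal (viewpoint-chromosome) interaction sites per
#' fixed 1 Mb bin, the profile used for replicate correlation, clustering
#' and PCA. A site straddling a bin boundary is assigned by its start
#' coordinate.
#'
#' @param sites Data.frame with `chrom` and `start` (e.g. significant
#'   windows or `high_fidelity_sites`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param chrom The viewpoint chromosome; sites elsewhere are ignored.
#' @param bin_size Bin width in bp (default 1e6).
#' @return Named integer vector of per-bin site counts, one element per
#'   bin of `chrom` (names `<chrom>:<bin start>`).
#' @export
bin_1mb <- function(sites, chrom_sizes, chrom, bin_size = 1e6) {
  stopifnot(chrom %in% names(chrom_sizes))
  len <- chrom_sizes[[chrom]]
  nbins <- ceiling(len / bin_size)
  cis <- sites[sites$chrom == chrom, , drop = FALSE]
  if (nrow(cis) && (any(cis$start < 0) || any(cis$start >= len))) {
    stop("site beyond chromosome bounds")
  }
  counts <- tabulate(cis$start %/% bin_size + 1L, nbins)
  names(counts) <- paste0(chrom, ":",
                          format(seq_len(nbins) - 1, scientific = FALSE,
                                 trim = TRUE))
  counts
}

#' Replicate correlation gate
#'
#' Pearson correlation between two replicates' 1 Mb binned interaction-site
#' profiles, with the standard acceptance gate `r > 0.4`.
#'
#' @param callsA,callsB `interaction_calls` of the two replicates.
#' @param chrom_sizes Named chromosome lengths.
#' @return List with `pearson` and `passes_corr_gate`.
#' @param corr_gate Gate threshold (strict `>`).
#' @export
replicate_correlation <- function(callsA, callsB, chrom_sizes,
                                  corr_gate = 0.4) {
  vp <- attr(callsA, "viewpoint")
  a <- bin_1mb(callsA[callsA$significant, ], chrom_sizes, vp$chrom)
  b <- bin_1mb(callsB[callsB$significant, ], chrom_sizes, vp$chrom)
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(a, b)
  list(pearson = r, passes_corr_gate = !is.na(r) && r > corr_gate)
}

#' Correlation matrix and hierarchical clustering of binned profiles
#'
#' Pairwise Pearson correlation of per-sample 1 Mb binned interaction-site
#' profiles, clustered by average linkage on the distance `1 - r`.
#' Zero-variance profiles get `NA` correlations and are excluded from
#' clustering. Samples are ordered by name before clustering so leaf order
#' is deterministic.
#'
#' @param profiles Named list of equal-length numeric vectors, or a matrix
#'   with samples in columns.
#' @return List with `correlation` (matrix), `hclust` (or `NULL` when
#'   fewer than two usable profiles) and `order` (leaf order as sample
#'   names).
#' @export
correlation_cluster <- function(profiles) {
  mat <- if (is.matrix(profiles)) profiles else do.call(cbind, profiles)
  stopifnot(ncol(mat) >= 2, !is.null(colnames(mat)))
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  r <- suppressWarnings(stats::cor(mat))
  degenerate <- apply(mat, 2, stats::sd) == 0
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r)[!degenerate] <- 1
  usable <- colnames(mat)[!degenerate]
  hc <- NULL
  ord <- usable
  if (length(usable) >= 2) {
    d <- stats::as.dist(1 - r[usable, usable])
    hc <- stats::hclust(d, method = "average")
    ord <- usable[hc$order]
  }
  list(correlation = r, hclust = hc, order = ord)
}

#' PCA of binned interaction profiles
#'
#' Centred (unscaled) principal component analysis of per-sample binned
#' profiles. Component signs are fixed by making the largest-magnitude
#' loading of each component positive, so results are reproducible across
#' platforms.
#'
#' @param profiles Named list of equal-length numeric vectors or a matrix
#'   with samples in columns.
#' @return List with `coordinates` (samples x components), `loadings` and
#'   `explained` (variance fractions summing to 1).
#' @export
pca_profiles <- function(profiles) {
  mat <- if (is.matrix(profiles)) profiles else do.call(cbind, profiles)
  stopifnot(ncol(mat) >= 2)
  x <- t(mat)  # samples in rows
  if (all(apply(x, 2, stats::sd) == 0)) {
    stop("all profiles are constant; PCA undefined")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(coordinates = pc$x, loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Overlap summary of two or three interaction-site sets
#'
#' Exact Venn partition counts for named window-id sets on a common grid,
#' plus the shared fraction `|intersection of all| / |union of all|`.
#'
#' @param sets Named list of 2 or 3 character vectors of window ids.
#' @return List with `sizes`, `partition` (named counts of every exclusive
#'   Venn region), `shared` (size of the common intersection), `union`
#'   and `shared_fraction`.
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (length(sets) < 2 || length(sets) > 3) {
    stop("overlap summaries are defined for 2 or 3 sets")
  }
  sets <- lapply(sets, unique)
  uni <- Reduce(union, sets)
  member <- vapply(sets, function(s) uni %in% s, logical(length(uni)))
  member <- matrix(member, nrow = length(uni),
                   dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(z)
    paste(names(sets)[z], collapse = "&"))
  partition <- table(pattern)
  shared <- length(Reduce(intersect, sets))
  list(sizes = vapply(sets, length, integer(1)),
       partition = stats::setNames(as.integer(partition), names(partition)),
       shared = shared, union = length(uni),
       shared_fraction = if (length(uni)) shared / length(uni) else NA_real_)
}
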