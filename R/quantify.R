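#' Remove artifact reads at the viewpoint
#'
#' Drops reads assigned to the viewpoint fragment itself (undigested
#' template) and to its two flanking fragments (self-ligation products),
#' the two artifact classes removed before any 4C quantification. All
#' other reads are retained unchanged.
#'
#' @param reads Read table (`sample`, `chrom`, `fragment_index`, `count`).
#' @param viewpoint A `viewpoint` (see [resolve_viewpoint()]).
#' @return The filtered read table, with attributes `removed_reads` (total
#'   count removed) and `total_reads` (input total).
#' @export
filter_invalid <- function(reads, viewpoint) {
  stopifnot(inherits(viewpoint, "viewpoint"),
            all(c("chrom", "fragment_index", "count") %in% names(reads)))
  bad_idx <- viewpoint$fragment_index + (-1L:1L)
  bad <- reads$chrom == viewpoint$chrom & reads$fragment_index %in% bad_idx
  out <- reads[!bad, , drop = FALSE]
  structure(out,
            removed_reads = sum(reads$count[bad]),
            total_reads = sum(reads$count))
}

#' Per-sample 4C quality report
#'
#' Computes the cis/overall read ratio -- the share of reads mapping to the
#' viewpoint chromosome -- and flags whether it clears the standard
#' quality gate of strictly more than 40%. Computed on unfiltered reads,
#' as artifact reads also sit on the viewpoint chromosome.
#'
#' @param reads Read table (before artifact filtering).
#' @param viewpoint A `viewpoint`.
#' @param cis_gate Gate threshold on the cis ratio (strict `>`).
#' @return A one-row data.frame of class `qc_report`: `sample`,
#'   `total_reads`, `cis_reads`, `cis_ratio`, `passes_cis_gate`.
#' @export
compute_qc <- function(reads, viewpoint, cis_gate = 0.40) {
  stopifnot(inherits(viewpoint, "viewpoint"))
  total <- sum(reads$count)
  if (total == 0) stop("cannot compute QC on zero reads")
  cis <- sum(reads$count[reads$chrom == viewpoint$chrom])
  out <- data.frame(
    sample = if ("sample" %in% names(reads)) reads$sample[1] else NA_character_,
    total_reads = total, cis_reads = cis, cis_ratio = cis / total,
    passes_cis_gate = (cis / total) > cis_gate)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Window counts and RPM normalization
#'
#' Credits every read to the fixed, non-overlapping window (default 2 kb)
#' containing its fragment's midpoint, over the full genome grid, and
#' normalizes counts to RPM (reads per million per window) against the
#' total of retained reads. Windows are grid-aligned at multiples of the
#' window size; the last window of a chromosome is truncated at the
#' chromosome end.
#'
#' @param reads Filtered read table.
#' @param fmap The `fragment_map` the fragment indices refer to.
#' @param window_size Window width in bp (default 2000).
#' @return A `window_track` data.frame: `chrom`, `start`, `end`,
#'   `window_id`, `count`, `rpm`, covering every grid window (zero rows
#'   included), with attributes `window_size` and `total_reads`.
#' @export
window_rpm <- function(reads, fmap, window_size = 2000) {
  stopifnot(inherits(fmap, "fragment_map"))
  if (window_size <= 0) stop("window size must be positive")
  window_size <- as.integer(window_size)
  grid <- do.call(rbind, lapply(names(fmap$chrom_sizes), function(chr) {
    len <- fmap$chrom_sizes[[chr]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + window_size, len))
  }))
  grid$window_id <- paste0(grid$chrom, ":", grid$start)

  fr <- fmap$fragments
  key <- paste0(fr$chrom, ":", fr$index)
  mid <- as.integer((fr$start + fr$end) %/% 2L)
  read_mid <- mid[match(paste0(reads$chrom, ":", reads$fragment_index), key)]
  if (anyNA(read_mid)) stop("reads reference fragments absent from the map")
  read_win <- paste0(reads$chrom, ":", (read_mid %/% window_size) * window_size)
  counts <- rowsum(reads$count, read_win)
  grid$count <- 0
  hit <- match(rownames(counts), grid$window_id)
  stopifnot(!anyNA(hit))
  grid$count[hit] <- counts[, 1]
  total <- sum(grid$count)
  grid$rpm <- if (total > 0) grid$count / total * 1e6 else 0
  structure(grid, window_size = window_size, total_reads = total,
            class = c("window_track", "data.frame"))
}

#' Call significantly interacting windows
#'
#' Identifies cis windows whose counts exceed a local distance-decay
#' background. Windows on the viewpoint chromosome are ordered by distance
#' from the viewpoint (windows overlapping viewpoint +/- `exclusion`
#' excluded: the over-represented near-cis zone would otherwise dominate
#' the fit); the background is a running median over `k` distance-ordered
#' windows, floored at `floor`; each window gets a one-sided upper-tail
#' Poisson p-value against its background, adjusted by Benjamini-Hochberg
#' across all tested windows. Trans windows are never tested: interaction
#' calls are cis-only.
#'
#' When `fmap` is supplied the background is fragment-density aware: the
#' running median is taken over per-fragment rates (window count divided
#' by the number of restriction-fragment midpoints in the window) and
#' rescaled by each window's fragment count. Windows hold a
#' Poisson-variable number of fragments, so a distance-only count median
#' leaves counts overdispersed and badly mis-calibrates the test;
#' normalizing by fragment density is the standard remedy in
#' fragment-based chromosome-conformation analysis. Without `fmap` the
#' plain count median is used (exact only under uniform fragment
#' density).
#'
#' @param track A `window_track`.
#' @param viewpoint A `viewpoint`.
#' @param fmap Optional `fragment_map` for the fragment-density-aware
#'   background (recommended; the pipeline always passes it).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param exclusion Viewpoint-proximal exclusion radius in bp (default
#'   10 kb).
#' @param k Running-median span in windows (odd; default 101).
#' @param floor Background floor in counts (default 0.5).
#' @return An `interaction_calls` data.frame (`chrom`, `start`, `end`,
#'   `window_id`, `count`, `distance`, `background`, `pvalue`, `padj`,
#'   `significant`), one row per tested cis window, in genomic order.
#' @export
call_interactions <- function(track, viewpoint, fmap = NULL, alpha = 0.05,
                              exclusion = 1e4, k = 101, floor = 0.5) {
  stopifnot(inherits(track, "window_track"), inherits(viewpoint, "viewpoint"))
  cis <- track[track$chrom == viewpoint$chrom, , drop = FALSE]
  if (nrow(cis) == 0) stop("no cis windows present for ", viewpoint$chrom)
  pos <- viewpoint$position
  keep <- cis$end <= pos - exclusion | cis$start >= pos + exclusion
  cis <- cis[keep, , drop = FALSE]
  if (nrow(cis) < k) {
    stop("fewer than ", k, " cis windows after viewpoint exclusion; ",
         "use a larger genome or a smaller running-median span")
  }
  mid <- (cis$start + cis$end) / 2
  cis$distance <- abs(mid - pos)
  ord <- order(cis$distance)
  if (!is.null(fmap)) {
    stopifnot(inherits(fmap, "fragment_map"))
    ws <- attr(track, "window_size")
    fr <- fmap$fragments[fmap$fragments$chrom == viewpoint$chrom, ,
                         drop = FALSE]
    fmid <- as.integer((fr$start + fr$end) %/% 2L)
    wid <- paste0(viewpoint$chrom, ":", (fmid %/% ws) * ws)
    m <- as.integer(table(factor(wid, levels = cis$window_id)))
    rate <- ifelse(m > 0, cis$count / pmax(m, 1L), 0)
    bg_rate <- stats::runmed(rate[ord], k = k, endrule = "median")
    bg <- numeric(nrow(cis))
    bg[ord] <- bg_rate
    cis$background <- pmax(bg * m, floor)
  } else {
    bg <- stats::runmed(cis$count[ord], k = k, endrule = "median")
    cis$background <- NA_real_
    cis$background[ord] <- pmax(bg, floor)
  }
  cis$pvalue <- stats::ppois(cis$count - 1, cis$background,
                             lower.tail = FALSE)
  cis$padj <- stats::p.adjust(cis$pvalue, method = "BH")
  cis$significant <- cis$padj < alpha
  out <- cis[order(cis$start),
             c("chrom", "start", "end", "window_id", "count", "distance",
               "background", "pvalue", "padj", "significant")]
  structure(out, window_size = attr(track, "window_size"),
            viewpoint = viewpoint, alpha = alpha,
            class = c("interaction_calls", "data.frame"))
}

#' Replicate-shared high-fidelity interaction sites
#'
#' Intersects the significant windows of two biological replicates; only
#' windows called in both are retained as high-fidelity interaction sites,
#' suppressing the random inter-nucleus collisions that dominate
#' single-replicate calls.
#'
#' @param repA,repB `interaction_calls` on the identical window grid.
#' @return A `high_fidelity_sites` data.frame (`chrom`, `start`, `end`,
#'   `window_id`) -- the subset of each replicate's significant set.
#' @export
high_fidelity <- function(repA, repB) {
  stopifnot(inherits(repA, "interaction_calls"),
            inherits(repB, "interaction_calls"))
  if (!identical(attr(repA, "window_size"), attr(repB, "window_size")) ||
      !identical(repA$window_id, repB$window_id)) {
    stop("replicate call sets are not on the same window grid")
  }
  ids <- intersect(repA$window_id[repA$significant],
                   repB$window_id[repB$significant])
  out <- repA[repA$window_id %in% ids,
              c("chrom", "start", "end", "window_id"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, window_size = attr(repA, "window_size"),
            class = c("high_fidelity_sites", "data.frame"))
}

#' Raw window counts for a set of windows across samples
#'
#' Assembles the count matrix consumed by [differential()]: one row per
#' requested window, one column per sample track.
#'
#' @param tracks Named list of `window_track` objects on a common grid.
#' @param window_ids Character vector of `window_id`s (rows of the result).
#' @return Integer matrix, `length(window_ids)` x `length(tracks)`.
#' @export
window_counts <- function(tracks, window_ids) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  mat <- vapply(tracks, function(tr) {
    i <- match(window_ids, tr$window_id)
    if (anyNA(i)) stop("window ids missing from a track")
    tr$count[i]
  }, numeric(length(window_ids)))
  mat <- matrix(mat, nrow = length(window_ids),
                dimnames = list(window_ids, names(tracks)))
  mat
}
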