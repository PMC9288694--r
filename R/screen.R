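as_granges0 <- function(df) {
  # 0-based half-open data.frame -> GRanges (1-based closed)
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Screen high-fidelity interaction sites for candidate active enhancers
#'
#' Implements the candidate-active-enhancer screen: (1) drop
#' interchromosomal sites; (2) keep sites overlapping (by at least
#' `min_overlap` bp) BOTH an H3K27ac peak and an ATAC peak; (3) drop
#' sites overlapping any annotated promoter; (4) merge adjacent surviving
#' windows into regions; (5) within each region emit the window of at most
#' `width_cap` bp with the maximum integrated ATAC signal as one candidate
#' enhancer. All intervals are 0-based half-open; overlap is half-open
#' (touching intervals do not overlap).
#'
#' @param interactions `high_fidelity_sites` (or any BED-like data.frame
#'   of interaction windows with `chrom`, `start`, `end`).
#' @param h3k27ac,atac,promoters BED-like peak data.frames.
#' @param atac_signal Signal step function (`chrom`, `start`, `end`,
#'   `value`).
#' @param viewpoint_chrom Viewpoint chromosome; sites elsewhere are
#'   interchromosomal and dropped.
#' @param width_cap Maximum candidate width in bp (default 1000).
#' @param min_overlap Minimum peak overlap in bp (default 1).
#' @return A `candidate_enhancers` data.frame: `chrom`, `start`, `end`,
#'   `region_start`, `region_end`, `signal` (integrated ATAC signal of the
#'   candidate window), `summit_value` (maximum signal height inside it),
#'   `n_h3k27ac`, `n_atac` (overlapping peak counts) and `zero_summit`.
#'   Empty interactions give an empty result, not an error.
#' @export
screen_enhancers <- function(interactions, h3k27ac, atac, promoters,
                             atac_signal, viewpoint_chrom,
                             width_cap = 1000, min_overlap = 1) {
  for (nm in c("interactions", "h3k27ac", "atac", "promoters",
               "atac_signal")) {
    if (is.null(get(nm))) stop("missing required input: ", nm)
  }
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_start = integer(0),
                      region_end = integer(0), signal = numeric(0),
                      summit_value = numeric(0), n_h3k27ac = integer(0),
                      n_atac = integer(0), zero_summit = logical(0))
  class(empty) <- c("candidate_enhancers", "data.frame")

  sites <- interactions[interactions$chrom == viewpoint_chrom, , drop = FALSE]
  if (nrow(sites) == 0) return(empty)
  gr <- as_granges0(sites)

  has_both <-
    GenomicRanges::countOverlaps(gr, as_granges0(h3k27ac),
                                 minoverlap = min_overlap) > 0 &
    GenomicRanges::countOverlaps(gr, as_granges0(atac),
                                 minoverlap = min_overlap) > 0
  gr <- gr[has_both]
  if (length(gr) == 0) return(empty)
  on_promoter <- GenomicRanges::countOverlaps(gr, as_granges0(promoters)) > 0
  gr <- gr[!on_promoter]
  if (length(gr) == 0) return(empty)

  regions <- GenomicRanges::reduce(gr)  # merges abutting windows
  out <- lapply(seq_along(regions), function(i) {
    a <- BiocGenerics::start(regions)[i] - 1L
    b <- BiocGenerics::end(regions)[i]
    win <- max_signal_window(atac_signal, viewpoint_chrom, a, b,
                             width_cap = width_cap)
    data.frame(chrom = viewpoint_chrom, start = win$start, end = win$end,
               region_start = a, region_end = b, signal = win$signal,
               summit_value = win$summit_value,
               zero_summit = win$zero_summit)
  })
  out <- do.call(rbind, out)
  cand_gr <- as_granges0(out)
  out$n_h3k27ac <- GenomicRanges::countOverlaps(cand_gr, as_granges0(h3k27ac))
  out$n_atac <- GenomicRanges::countOverlaps(cand_gr, as_granges0(atac))
  out <- out[order(out$start),
             c("chrom", "start", "end", "region_start", "region_end",
               "signal", "summit_value", "n_h3k27ac", "n_atac",
               "zero_summit")]
  rownames(out) <- NULL
  structure(out, width_cap = width_cap,
            class = c("candidate_enhancers", "data.frame"))
}

#' Maximum-signal window within a region
#'
#' Finds the window of length `min(width_cap, region length)` inside
#' `[region_start, region_end)` maximizing the integrated signal (sum of
#' value x covered bp); ties are broken by the leftmost start. The
#' integrated score as a function of the window start is piecewise linear
#' with breakpoints at signal-run boundaries, so the optimum is found by
#' evaluating the cumulative signal integral at run boundaries and their
#' `width`-shifted images.
#'
#' @param signal Step-function data.frame (`chrom`, `start`, `end`,
#'   `value`), runs non-overlapping within a chromosome.
#' @param chrom,region_start,region_end The target region (0-based
#'   half-open).
#' @param width_cap Maximum window width in bp.
#' @return List with `start`, `end`, `signal` (integrated), `summit_value`
#'   (maximum run value inside the window) and `zero_summit` (`TRUE` when
#'   the whole region carries zero signal, in which case the leftmost
#'   window is returned).
#' @export
max_signal_window <- function(signal, chrom, region_start, region_end,
                              width_cap = 1000) {
  stopifnot(width_cap > 0, region_end > region_start)
  w <- min(width_cap, region_end - region_start)
  runs <- signal[signal$chrom == chrom &
                   signal$end > region_start & signal$start < region_end, ,
                 drop = FALSE]
  runs$start <- pmax(runs$start, region_start)
  runs$end <- pmin(runs$end, region_end)
  runs <- runs[order(runs$start), , drop = FALSE]

  if (nrow(runs) == 0 || all(runs$value == 0)) {
    return(list(start = region_start, end = region_start + w, signal = 0,
                summit_value = 0, zero_summit = TRUE))
  }
  # cumulative integral at breakpoints, linear in between (value constant
  # inside a run, zero in gaps)
  bp <- sort(unique(c(region_start, region_end, runs$start, runs$end)))
  cum <- numeric(length(bp))
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]; e <- runs$end[i]; v <- runs$value[i]
    cum <- cum + v * (pmin(pmax(bp, s), e) - s)
  }
  integral <- stats::approxfun(bp, cum, rule = 2)
  cand <- sort(unique(c(region_start, region_end - w, bp, bp - w)))
  cand <- cand[cand >= region_start & cand <= region_end - w]
  score <- integral(cand + w) - integral(cand)
  best <- max(score)
  s0 <- cand[which(score >= best - 1e-9)[1]]  # leftmost tie
  win_runs <- runs[runs$end > s0 & runs$start < s0 + w, , drop = FALSE]
  list(start = s0, end = s0 + w,
       signal = integral(s0 + w) - integral(s0),
       summit_value = if (nrow(win_runs)) max(win_runs$value) else 0,
       zero_summit = FALSE)
}

#' Annotate candidate enhancers with conserved-element overlap
#'
#' Flags each candidate that overlaps (by at least 1 bp, half-open) at
#' least one conserved element, and reports the conserved fraction.
#'
#' @param candidates A `candidate_enhancers` data.frame.
#' @param conserved BED-like data.frame of conserved elements.
#' @return `candidates` with a logical `conserved` column and attribute
#'   `conserved_fraction` (conserved count / total; 0 for an empty
#'   conserved set).
#' @export
annotate_conservation <- function(candidates, conserved) {
  if (nrow(candidates) == 0) {
    candidates$conserved <- logical(0)
    attr(candidates, "conserved_fraction") <- NA_real_
    return(candidates)
  }
  if (is.null(conserved) || nrow(conserved) == 0) {
    candidates$conserved <- FALSE
  } else {
    hits <- GenomicRanges::countOverlaps(as_granges0(candidates),
                                         as_granges0(conserved))
    candidates$conserved <- hits > 0
  }
  attr(candidates, "conserved_fraction") <-
    sum(candidates$conserved) / nrow(candidates)
  candidates
}

#' Width of a printed genomic span
#'
#' Parses a human-readable span such as
#' `"chr11:67,104,519-67,142,456"` (hyphen, en or em dash; comma
#' thousands separators) and returns its width and the nearest-kb
#' rounding.
#'
#' @param span Character scalar of the form `chrom:start-end`.
#' @return List with `chrom`, `start`, `end`, `width_bp` (`end - start`)
#'   and `width_kb` (`round(width / 1000)`).
#' @export
region_width <- function(span) {
  stopifnot(is.character(span), length(span) == 1L)
  m <- regmatches(span, regexec(
    "^\\s*([^:]+):\\s*([0-9,]+)\\s*[-–—]\\s*([0-9,]+)\\s*$", span))[[1]]
  if (length(m) != 4) stop("cannot parse genomic span: '", span, "'")
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (end <= start) stop("span end must exceed start: '", span, "'")
  list(chrom = m[2], start = start, end = end, width_bp = end - start,
       width_kb = round((end - start) / 1000))
}
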