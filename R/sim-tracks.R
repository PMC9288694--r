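#' Simulate epigenomic companion tracks
#'
#' Emits the peak and signal inputs the enhancer screen consumes, co-located
#' with the planted enhancers: an H3K27ac peak and an ATAC peak covering
#' every planted summit (centre jittered by at most `jitter` bp), a
#' step-function ATAC signal on the viewpoint chromosome made of Gaussian
#' bumps (sd 150 bp) at the summits over low uniform noise, a promoter
#' interval of viewpoint +/- 1 kb, conserved elements at the summits, and
#' decoy peaks placed far from every enhancer. Decoy H3K27ac and ATAC peaks
#' are disjoint from one another, so decoys can never satisfy the
#' both-marks screening rule.
#'
#' @param config A [sim_config()].
#' @param truth The matching [sim_truth()].
#' @param peak_width Width of emitted peaks (bp).
#' @param jitter Maximum absolute jitter of peak centres around the summit
#'   (bp); must stay below `peak_width / 2` so the summit remains covered.
#' @param n_decoys Decoy peaks per mark.
#' @param signal_bin Resolution of the ATAC signal step function (bp).
#' @param bump_height Amplitude of the Gaussian ATAC bump at each summit.
#' @return A list of data.frames: `h3k27ac`, `atac`, `promoters`,
#'   `conserved` (BED-like, 0-based half-open, with `name` column) and
#'   `atac_signal` (`chrom`, `start`, `end`, `value`). Deterministic for a
#'   fixed `config$seed`.
#' @export
simulate_tracks <- function(config, truth, peak_width = 800, jitter = 200,
                            n_decoys = 4, signal_bin = 50,
                            bump_height = 20) {
  config <- validate_sim_config(config)
  stopifnot(jitter < peak_width / 2)
  vp <- truth$viewpoint
  chrom_len <- config$chrom_sizes[[vp$chrom]]
  set.seed((abs(config$seed) * 613L + 13L) %% .Machine$integer.max)

  pl <- truth$planted
  stopifnot(all(pl$chrom == vp$chrom))
  summits <- pl$summit

  peak_at <- function(centres, label, offset = 0) {
    centres <- pmin(pmax(centres, peak_width / 2), chrom_len - peak_width / 2)
    data.frame(chrom = vp$chrom,
               start = as.integer(round(centres - peak_width / 2)),
               end = as.integer(round(centres + peak_width / 2)),
               name = paste0(label, "_", seq_along(centres) + offset))
  }
  jit <- function(n) sample(seq(-jitter, jitter), n, replace = TRUE)

  h3k27ac <- peak_at(summits + jit(length(summits)), "h3k27ac")
  atac <- peak_at(summits + jit(length(summits)), "atac")

  # decoys: >= 50 kb from any summit and from the viewpoint, marks disjoint
  keepout <- c(summits, vp$position)
  draw_decoys <- function(n, avoid) {
    pos <- integer(0)
    while (length(pos) < n) {
      cand <- sample.int(chrom_len - peak_width, n * 4) + peak_width / 2
      ok <- vapply(cand, function(x) {
        all(abs(x - keepout) > 5e4) && all(abs(x - avoid) > 2 * peak_width)
      }, logical(1))
      pos <- c(pos, cand[ok])
    }
    pos[seq_len(n)]
  }
  if (n_decoys > 0) {
    dk <- draw_decoys(n_decoys, avoid = integer(0))
    da <- draw_decoys(n_decoys, avoid = dk)
    h3k27ac <- rbind(h3k27ac, peak_at(dk, "h3k27ac_decoy"))
    atac <- rbind(atac, peak_at(da, "atac_decoy"))
  }
  h3k27ac <- h3k27ac[order(h3k27ac$start), ]
  atac <- atac[order(atac$start), ]

  # ATAC signal: Gaussian bumps over uniform noise, binned step function
  starts <- seq.int(0L, chrom_len - 1L, by = signal_bin)
  mids <- starts + signal_bin / 2
  value <- stats::runif(length(starts), 0, 0.5)
  for (s in summits) {
    value <- value + bump_height * exp(-(mids - s)^2 / (2 * 150^2))
  }
  atac_signal <- data.frame(chrom = vp$chrom, start = starts,
                            end = pmin(starts + signal_bin, chrom_len),
                            value = value)

  promoters <- data.frame(chrom = vp$chrom,
                          start = max(0L, vp$position - 1000L),
                          end = min(chrom_len, vp$position + 1000L),
                          name = "viewpoint_promoter")

  conserved <- data.frame(chrom = vp$chrom,
                          start = as.integer(summits - 100),
                          end = as.integer(summits + 100),
                          name = paste0("conserved_", seq_along(summits)))

  list(h3k27ac = h3k27ac, atac = atac, promoters = promoters,
       conserved = conserved, atac_signal = atac_signal)
}
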