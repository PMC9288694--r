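#' Ground truth of a simulated experiment
#'
#' Resolves the viewpoint, computes per-fragment cis contact weights under
#' the power-law decay `(1 + d/d0)^(-alpha)` and applies every planted
#' enhancer's per-condition multiplicative effect to the fragments whose
#' midpoint falls inside its footprint. The viewpoint fragment and its two
#' neighbours carry weight zero: valid cis reads never originate there
#' (artifact reads are drawn separately).
#'
#' @param config A [sim_config()].
#' @param fmap The `fragment_map` of the simulated genome.
#' @return A `sim_truth` list: `viewpoint`, `planted` (data.frame with
#'   per-condition effect columns), `cis_fragments` (cis fragment table
#'   with midpoints and distances) and `weights` (fragment x condition
#'   matrix of unnormalized contact weights).
#' @export
sim_truth <- function(config, fmap) {
  config <- validate_sim_config(config)
  vp <- resolve_viewpoint(fmap, config$viewpoint$chrom,
                          config$viewpoint$position, name = "viewpoint")
  cis <- fmap$fragments[fmap$fragments$chrom == vp$chrom, ]
  cis$mid <- (cis$start + cis$end) %/% 2L
  cis$distance <- abs(cis$mid - vp$position)
  base <- (1 + cis$distance / config$decay_d0)^(-config$decay_alpha)
  base[abs(cis$index - vp$fragment_index) <= 1L] <- 0
  w <- matrix(base, nrow = nrow(cis), ncol = length(config$conditions),
              dimnames = list(NULL, config$conditions))
  for (pe in config$planted) {
    if (pe$chrom != vp$chrom) next
    lo <- pe$summit - pe$width / 2
    hi <- pe$summit + pe$width / 2
    in_fp <- cis$mid >= lo & cis$mid < hi
    for (cond in config$conditions) {
      w[in_fp, cond] <- w[in_fp, cond] * pe$effect[[cond]]
    }
  }
  planted <- do.call(rbind, lapply(config$planted, function(pe) {
    row <- data.frame(chrom = pe$chrom, summit = pe$summit, width = pe$width)
    for (cond in config$conditions) row[[paste0("effect_", cond)]] <-
        pe$effect[[cond]]
    row
  }))
  structure(list(viewpoint = vp, planted = planted, cis_fragments = cis,
                 weights = w),
            class = "sim_truth")
}

#' Expected per-window contact intensity
#'
#' Aggregates the truth's fragment weights to the 2 kb window grid of the
#' viewpoint chromosome, normalized to sum to 1 per condition. Windows
#' holding a planted enhancer have intensity at least the local background
#' by construction (effects are `>= 1`).
#'
#' @param truth A [sim_truth()] object.
#' @param window_size Window width in bp.
#' @return A data.frame `chrom`, `start`, `end` and one intensity column
#'   per condition.
#' @export
truth_window_intensity <- function(truth, window_size = 2000) {
  cis <- truth$cis_fragments
  win <- (cis$mid %/% window_size) * window_size
  agg <- rowsum(truth$weights, win)
  starts <- as.integer(rownames(agg))
  out <- data.frame(chrom = truth$viewpoint$chrom, start = starts,
                    end = starts + as.integer(window_size))
  for (cond in colnames(agg)) out[[cond]] <- agg[, cond] / sum(agg[, cond])
  out[order(out$start), ]
}

#' Simulate one 4C-seq sample at fragment resolution
#'
#' Emits exactly `n_reads` reads split multinomially into three classes:
#' artifact reads (`invalid_fraction`; half undigested on the viewpoint
#' fragment, a quarter self-ligated on each flanking fragment), valid cis
#' reads (`cis_fraction - invalid_fraction`; drawn over cis fragments with
#' probability proportional to the truth's decay-and-effect weights,
#' perturbed by a per-fragment mean-1 Gamma multiplier of variance
#' `noise_dispersion`) and trans reads (uniform over the base pairs of the
#' other chromosomes, i.e. fragment probability proportional to length).
#' Deterministic given `(seed, condition, replicate)`.
#'
#' @param config A [sim_config()].
#' @param fmap The genome's `fragment_map`.
#' @param truth The matching [sim_truth()].
#' @param condition Condition label (must appear in `config$conditions`).
#' @param replicate Replicate number (1-based).
#' @return A data.frame `sample`, `chrom`, `fragment_index`, `count`
#'   (fragments with zero reads omitted; counts sum to `n_reads`).
#' @export
simulate_sample <- function(config, fmap, truth, condition, replicate = 1L) {
  config <- validate_sim_config(config)
  if (config$n_reads <= 0) stop("n_reads must be positive")
  vp <- truth$viewpoint
  set.seed(sample_seed(config, condition, replicate))

  p_inv <- config$invalid_fraction
  p_cis <- config$cis_fraction - config$invalid_fraction
  p_trans <- 1 - config$cis_fraction
  n_class <- as.vector(stats::rmultinom(1, config$n_reads,
                                        c(p_inv, p_cis, p_trans)))

  cis <- truth$cis_fragments
  w <- truth$weights[, condition]
  if (config$noise_dispersion > 0) {
    shape <- 1 / config$noise_dispersion
    w <- w * stats::rgamma(length(w), shape = shape, rate = shape)
  }
  counts <- list()

  if (n_class[1] > 0) {  # artifact: undigested + self-ligated
    vp_idx <- vp$fragment_index
    neigh <- intersect(c(vp_idx - 1L, vp_idx + 1L), cis$index)
    targets <- c(vp_idx, neigh)
    probs <- c(0.5, rep(0.25, length(neigh)))
    k <- as.vector(stats::rmultinom(1, n_class[1], probs))
    counts[[1]] <- data.frame(chrom = vp$chrom, fragment_index = targets,
                              count = k)
  }
  if (n_class[2] > 0) {  # valid cis, decay + planted effects
    if (sum(w) <= 0) stop("no cis fragments with positive weight")
    k <- as.vector(stats::rmultinom(1, n_class[2], w / sum(w)))
    counts[[2]] <- data.frame(chrom = vp$chrom, fragment_index = cis$index,
                              count = k)
  }
  if (n_class[3] > 0) {  # trans, uniform over bp of other chromosomes
    tf <- fmap$fragments[fmap$fragments$chrom != vp$chrom, ]
    if (nrow(tf) == 0) stop("no trans chromosomes to place trans reads on")
    k <- as.vector(stats::rmultinom(1, n_class[3],
                                    (tf$end - tf$start) /
                                      sum(tf$end - tf$start)))
    counts[[3]] <- data.frame(chrom = tf$chrom, fragment_index = tf$index,
                              count = k)
  }
  out <- do.call(rbind, counts)
  out <- stats::aggregate(count ~ chrom + fragment_index, out, sum)
  out <- out[out$count > 0, ]
  out <- out[order(out$chrom, out$fragment_index), ]
  out <- data.frame(sample = paste0(condition, "_rep", replicate), out,
                    row.names = NULL)
  stopifnot(sum(out$count) == config$n_reads)
  out
}

#' Simulate every sample of the configured design
#'
#' Convenience wrapper crossing `conditions` x `replicates` through
#' [simulate_sample()].
#'
#' @param config A [sim_config()].
#' @param fmap,truth Genome fragment map and truth, from [make_genome()]
#'   and [sim_truth()].
#' @return Named list of read tables, one per sample, names
#'   `<condition>_rep<k>`.
#' @export
simulate_experiment <- function(config, fmap, truth) {
  out <- list()
  for (cond in config$conditions) {
    for (rep in seq_len(config$replicates)) {
      s <- simulate_sample(config, fmap, truth, cond, rep)
      out[[s$sample[1]]] <- s
    }
  }
  out
}
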