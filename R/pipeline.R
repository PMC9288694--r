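#' Run the full simulated 4C analysis end to end
#'
#' Executes every stage of the pipeline on a simulated experiment:
#' genome + fragment map, per-sample reads, artifact filtering and QC,
#' 2 kb window RPM tracks, per-replicate interaction calls, replicate
#' correlation and high-fidelity intersection per condition, differential
#' analysis of the union of high-fidelity sites between the two
#' conditions, the enhancer screen against the simulated H3K27ac/ATAC
#' peaks and ATAC signal per condition, conservation annotation, and
#' E-box/PWM motif scanning of the candidate sequences.
#'
#' @param sim A [sim_config()] defining the experiment (two conditions
#'   required for the differential stage).
#' @param config A [pipeline_config()] of analysis thresholds.
#' @param pwms Optional list of [pwm()] objects for the motif stage;
#'   defaults to the synthetic myogenic-factor matrices shipped with the
#'   package.
#' @param out_dir Optional directory; when given, every stage output is
#'   written there as plain text (FASTA, BED, bedGraph, TSV, JSON) and a
#'   run log records every threshold used, the seed and a configuration
#'   hash. Rerunning with the same configuration is byte-identical.
#' @return A `fourc_run` list: `truth`, `qc`, `tracks` (window tracks),
#'   `calls`, `correlation`, `high_fidelity`, `differential`,
#'   `candidates` (per condition, conservation-annotated), `motifs`,
#'   `config`, `sim`.
#' @export
run_pipeline <- function(sim, config = pipeline_config(), pwms = NULL,
                         out_dir = NULL) {
  sim <- validate_sim_config(sim)
  stopifnot(inherits(config, "pipeline_config"))
  if (length(sim$conditions) != 2 || sim$replicates < 2) {
    stop("the standard pipeline needs 2 conditions x >= 2 replicates")
  }
  log_lines <- c(
    paste0("fourCscreen run, seed=", sim$seed,
           ", config_hash=", config_hash(config)),
    paste0("thresholds: window_size=", config$window_size,
           " bin_size=", config$bin_size, " alpha=", config$alpha,
           " lfc_min=", config$lfc_min, " cis_gate=", config$cis_gate,
           " corr_gate=", config$corr_gate, " width_cap=", config$width_cap,
           " min_overlap=", config$min_overlap,
           " exclusion=", config$exclusion))

  gen <- make_genome(sim)
  truth <- sim_truth(sim, gen$fmap)
  vp <- truth$viewpoint
  reads <- simulate_experiment(sim, gen$fmap, truth)
  tracksim <- simulate_tracks(sim, truth)

  qc <- list(); wtracks <- list(); calls <- list()
  for (nm in names(reads)) {
    qc[[nm]] <- compute_qc(reads[[nm]], vp, cis_gate = config$cis_gate)
    filt <- filter_invalid(reads[[nm]], vp)
    wtracks[[nm]] <- window_rpm(filt, gen$fmap,
                                window_size = config$window_size)
    calls[[nm]] <- call_interactions(wtracks[[nm]], vp, fmap = gen$fmap,
                                     alpha = config$alpha,
                                     exclusion = config$exclusion)
  }
  qc <- do.call(rbind, qc)

  correlation <- list(); hf <- list(); candidates <- list()
  for (cond in sim$conditions) {
    reps <- paste0(cond, "_rep", seq_len(sim$replicates))
    correlation[[cond]] <- replicate_correlation(
      calls[[reps[1]]], calls[[reps[2]]], sim$chrom_sizes,
      corr_gate = config$corr_gate)
    hf[[cond]] <- high_fidelity(calls[[reps[1]]], calls[[reps[2]]])
    cand <- screen_enhancers(hf[[cond]], tracksim$h3k27ac, tracksim$atac,
                             tracksim$promoters, tracksim$atac_signal,
                             viewpoint_chrom = vp$chrom,
                             width_cap = config$width_cap,
                             min_overlap = config$min_overlap)
    candidates[[cond]] <- annotate_conservation(cand, tracksim$conserved)
  }

  union_ids <- sort(unique(c(hf[[1]]$window_id, hf[[2]]$window_id)))
  diff <- NULL
  if (length(union_ids)) {
    mat <- window_counts(wtracks, union_ids)
    # size factors from the full window grid: the high-fidelity selection
    # is signal-enriched, so per-selection median-of-ratios would absorb
    # real condition effects
    full <- window_counts(wtracks, wtracks[[1]]$window_id)
    sf <- compute_size_factors(full)
    cond_of <- sub("_rep[0-9]+$", "", colnames(mat))
    diff <- differential(mat, factor(cond_of, levels = sim$conditions),
                         lfc_min = config$lfc_min, alpha = config$alpha,
                         size_factors = sf)
  }

  motifs <- NULL
  all_cand <- do.call(rbind, lapply(candidates, function(x)
    x[, c("chrom", "start", "end")]))
  all_cand <- unique(all_cand)
  if (!is.null(all_cand) && nrow(all_cand)) {
    if (is.null(pwms)) {
      pwms <- read_jaspar(system.file("extdata", "synthetic_mrf_pwms.txt",
                                      package = "fourCscreen"))
    }
    seqs <- candidate_sequences(gen$genome, all_cand)
    motifs <- rank_motifs(seqs, pwms)
  }

  run <- list(truth = truth, qc = qc, tracks = wtracks, calls = calls,
              correlation = correlation, high_fidelity = hf,
              differential = diff, candidates = candidates,
              motifs = motifs, config = config, sim = sim,
              genome = gen$genome, fmap = gen$fmap, sim_tracks = tracksim,
              log = log_lines)
  class(run) <- "fourc_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_genome_fasta(run$genome, p("genome.fa"))
  export_fragment_bed(run$fmap, p("fragments.bed"))
  utils::write.table(run$qc, p("qc_report.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(run$tracks)) {
    tr <- run$tracks[[nm]]
    write_bedgraph(data.frame(chrom = tr$chrom, start = tr$start,
                              end = tr$end, value = tr$rpm),
                   p(paste0(nm, "_rpm.bedGraph")))
    sig <- run$calls[[nm]]
    write_bed(sig[sig$significant, c("chrom", "start", "end", "window_id")],
              p(paste0(nm, "_significant.bed")))
  }
  for (cond in names(run$high_fidelity)) {
    write_bed(run$high_fidelity[[cond]],
              p(paste0(cond, "_high_fidelity.bed")))
    write_bed(run$candidates[[cond]], p(paste0(cond, "_candidates.bed")))
  }
  if (!is.null(run$differential)) {
    utils::write.table(run$differential, p("differential.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$motifs)) {
    utils::write.table(run$motifs, p("motif_ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$truth$planted, p("truth_planted.json"),
                       dataframe = "rows", digits = NA)
  writeLines(run$log, p("run.log"))
  invisible(out_dir)
}

#' @export
print.fourc_run <- function(x, ...) {
  cat("<fourc_run> seed", x$sim$seed, "\n")
  cat("  samples:", nrow(x$qc), " cis ratios:",
      paste(sprintf("%.2f", x$qc$cis_ratio), collapse = " "), "\n")
  for (cond in names(x$high_fidelity)) {
    cat("  ", cond, ": ", nrow(x$high_fidelity[[cond]]),
        " high-fidelity sites, ", nrow(x$candidates[[cond]]),
        " candidate enhancers\n", sep = "")
  }
  if (!is.null(x$differential)) {
    cat("  differential:", nrow(x$differential), "sites,",
        sum(x$differential$sdis), "SDIS\n")
  }
  invisible(x)
}

#' Recovery of planted enhancers by a pipeline run
#'
#' Compares a run's outputs against its simulation truth: the fraction of
#' planted summits recovered as a candidate enhancer within `tol` bp (in
#' the condition with the larger planted effect), and the fraction of
#' condition-specific planted summits whose window is flagged SDIS.
#'
#' @param run A `fourc_run`.
#' @param tol Distance tolerance in bp between a planted summit and the
#'   midpoint of the matched candidate (default 500).
#' @return List with `summit_recovery` and `sdis_recovery` (each in
#'   `[0, 1]`; `sdis_recovery` is `NA` when no planted enhancer is
#'   condition-specific).
#' @export
planted_recovery <- function(run, tol = 500) {
  pl <- run$truth$planted
  conds <- run$sim$conditions
  eff <- as.matrix(pl[, paste0("effect_", conds)])
  strong_cond <- conds[max.col(eff, ties.method = "first")]
  hit <- vapply(seq_len(nrow(pl)), function(i) {
    cand <- run$candidates[[strong_cond[i]]]
    if (is.null(cand) || nrow(cand) == 0) return(FALSE)
    mid <- (cand$start + cand$end) / 2
    any(abs(mid - pl$summit[i]) <= tol)
  }, logical(1))
  specific <- abs(log2(eff[, 2] / eff[, 1])) > 0
  sdis_hit <- NA_real_
  if (any(specific) && !is.null(run$differential)) {
    ws <- attr(run$tracks[[1]], "window_size")
    d <- run$differential
    sdis_hit <- mean(vapply(which(specific), function(i) {
      # any window overlapping the planted contact footprint flagged SDIS
      lo <- ((pl$summit[i] - pl$width[i] %/% 2L) %/% ws) * ws
      hi <- ((pl$summit[i] + pl$width[i] %/% 2L - 1L) %/% ws) * ws
      ids <- paste0(pl$chrom[i], ":",
                    format(seq(lo, hi, by = ws), scientific = FALSE,
                           trim = TRUE))
      any(d$sdis[match(ids, d$window_id)], na.rm = TRUE)
    }, logical(1)))
  }
  list(summit_recovery = mean(hit), sdis_recovery = sdis_hit)
}
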