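# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles deliberately use naive enumeration, not the package's
# own code paths.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# all 0-based offsets where `site` (IUPAC) matches `seq` (literal chars)
brute_motif_offsets <- function(seq, site) {
  sq <- strsplit(toupper(seq), "")[[1]]
  st <- strsplit(toupper(site), "")[[1]]
  n <- length(sq); k <- length(st)
  if (k > n) return(integer(0))
  hits <- integer(0)
  for (o in 0:(n - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!sq[o + j] %in% iupac_table[[st[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, o)
  }
  hits
}

# fragments by naive scan: cut at every motif start
brute_digest <- function(seq, site) {
  len <- nchar(seq)
  cuts <- brute_motif_offsets(seq, site)
  bounds <- sort(unique(c(0L, cuts[cuts > 0 & cuts < len], len)))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             index = seq_len(length(bounds) - 1L))
}

# containing fragment by linear scan
brute_containing_fragment <- function(frags, position) {
  for (i in seq_len(nrow(frags))) {
    if (frags$start[i] <= position && position < frags$end[i]) {
      return(frags$index[i])
    }
  }
  NA_integer_
}

# integrated-signal window by exhaustive scan over every integer start
brute_max_signal_window <- function(signal, chrom, a, b, width_cap) {
  w <- min(width_cap, b - a)
  runs <- signal[signal$chrom == chrom & signal$end > a & signal$start < b, ,
                 drop = FALSE]
  best <- -Inf; best_s <- a
  for (s in a:(b - w)) {
    sc <- 0
    for (i in seq_len(nrow(runs))) {
      ov <- min(runs$end[i], s + w) - max(runs$start[i], s)
      if (ov > 0) sc <- sc + ov * runs$value[i]
    }
    if (sc > best) { best <- sc; best_s <- s }
  }
  list(start = best_s, end = best_s + w, signal = max(best, 0))
}

revcomp_chr <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

# E-box hits on both strands, deduplicated, by character comparison
brute_ebox <- function(seq) {
  seq <- toupper(seq)
  fwd <- brute_motif_offsets(seq, "CANNTG")
  n <- nchar(seq)
  rev_hits <- brute_motif_offsets(revcomp_chr(seq), "CANNTG")
  # map reverse offsets back to forward coordinates
  rev_fwd <- n - 6 - rev_hits
  sort(unique(c(fwd, rev_fwd)))
}

# best PWM hit by scoring every offset and strand from first principles
brute_pwm_best <- function(seq, p) {
  seq <- toupper(seq)
  L <- ncol(p$matrix)
  bits <- function(base, j) {
    if (base == "N") return(0)
    b <- match(base, c("A", "C", "G", "T"))
    log2((p$matrix[b, j] + p$pseudocount * p$background[b]) /
           ((1 + p$pseudocount) * p$background[b]))
  }
  n <- nchar(seq)
  scores <- offs <- numeric(0)
  for (o in 0:(n - L)) {
    win <- substr(seq, o + 1, o + L)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") win else revcomp_chr(win)
      chars <- strsplit(s, "")[[1]]
      sc <- sum(vapply(seq_len(L), function(j) bits(chars[j], j), 0))
      scores <- c(scores, sc); offs <- c(offs, o)
    }
  }
  best <- max(scores)
  # every offset within float tolerance of the optimum: ties (e.g. from N
  # positions scoring 0) may be broken either way under float summation
  list(score = best, offsets = sort(unique(offs[scores >= best - 1e-9])))
}

# a random PWM with columns summing to 1
rand_pwm <- function(L, name = "rand") {
  m <- matrix(stats::rexp(4 * L), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  pwm(name, m)
}

# tiny deterministic fragment map from an explicit sequence set
toy_fmap <- function(seqs, enzyme = "DpnII") {
  build_fragment_map(Biostrings::DNAStringSet(seqs), enzyme)
}

# compact simulation for unit tests (not the default study conditions)
tiny_sim <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               chrom_sizes = c(chr1 = 1.2e6, chr2 = 2e5),
               viewpoint = list(chrom = "chr1", position = 6e5),
               n_reads = 5e4,
               planted = list(planted_enhancer(
                 "chr1", 3e5, width = 2000,
                 effect = c(quadriceps = 1, soleus = 8))))
  over <- list(...)
  args[names(over)] <- over   # plain replacement, never recursive merging
  do.call(sim_config, args)
}
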