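#' Scan a sequence for E-boxes
#'
#' Finds every occurrence of the degenerate E-box motif `CANNTG` (the
#' binding element of the myogenic regulatory factors MYOD/MYOG), with
#' overlapping occurrences included. As a pattern class `CANNTG` is its
#' own reverse complement, so forward- and reverse-strand hit positions
#' coincide and each is reported once with strand `"+"`. `N` in the
#' sequence never matches.
#'
#' @param sequence DNA string (character scalar), case-insensitive.
#' @return A data.frame `offset` (0-based), `strand`, `match`. Empty for
#'   an empty sequence.
#' @export
ebox_scan <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- toupper(sequence)
  if (nchar(seq) < 6) {
    return(data.frame(offset = integer(0), strand = character(0),
                      match = character(0)))
  }
  m <- gregexpr("(?=CA[ACGT]{2}TG)", seq, perl = TRUE)[[1]]
  off <- as.integer(m)
  off <- off[off > 0] - 1L  # 0-based; gregexpr returns -1 on no match
  if (!length(off)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      match = character(0)))
  }
  data.frame(offset = off, strand = "+",
             match = substring(seq, off + 1L, off + 6L))
}

#' Construct a position weight matrix
#'
#' A PWM holds per-position base probabilities (rows A, C, G, T), a
#' pseudocount and a background distribution. Scores are log-odds in bits:
#' at each position `log2((p + pseudocount * bg) / ((1 + pseudocount) *
#' bg))`, so the pseudocount bounds scores away from minus infinity; an
#' `N` in the scanned sequence contributes 0 at its position.
#'
#' @param name Motif name.
#' @param matrix 4 x L numeric matrix of probabilities (rows in A, C, G, T
#'   order); columns must sum to 1 within `tol` (counts should be
#'   normalized first, as [read_jaspar()] does).
#' @param pseudocount Pseudocount (default 0.01).
#' @param background Background base probabilities (default uniform).
#' @param tol Column-sum tolerance.
#' @return A `pwm` object.
#' @export
pwm <- function(name, matrix, pseudocount = 0.01,
                background = rep(0.25, 4), tol = 1e-6) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == 4, ncol(matrix) >= 1, all(matrix >= 0),
            length(background) == 4, all(background > 0),
            pseudocount >= 0)
  if (any(abs(colSums(matrix) - 1) > tol)) {
    stop("PWM columns must sum to 1; normalize counts first")
  }
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = matrix, pseudocount = pseudocount,
                 background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$name, "length", ncol(x$matrix), "\n")
  invisible(x)
}

#' Read JASPAR-style PWM files
#'
#' Parses plain-text matrices of the form
#' `>MA0500.1 MYOG` followed by four lines `A [ 10 20 ... ]` (brackets
#' optional), one or more motifs per file. Counts are normalized to
#' column probabilities.
#'
#' @param path Path to a JASPAR-format text file.
#' @param pseudocount,background Passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01,
                        background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no motif headers ('>') found in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4) stop("motif block with fewer than 4 base rows")
    name <- trimws(sub("^>\\s*", "", lines[heads[i]]))
    name <- gsub("\\s+", "_", name)
    rows <- lapply(block[1:4], function(l) {
      nums <- regmatches(l, gregexpr("[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    base_order <- toupper(substr(trimws(block[1:4]), 1, 1))
    mat <- do.call(rbind, rows)
    if (all(c("A", "C", "G", "T") %in% base_order)) {
      mat <- mat[match(c("A", "C", "G", "T"), base_order), , drop = FALSE]
    }
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[name]] <- pwm(name, mat, pseudocount = pseudocount,
                       background = background)
  }
  out
}

# bits score matrix (4+1 rows: A C G T N) for one strand
pwm_bits <- function(p) {
  s <- log2(sweep(p$matrix, 1, p$pseudocount * p$background, "+") /
              ((1 + p$pseudocount) * p$background))
  rbind(s, N = 0)
}

seq_codes <- function(seq) {
  chartr_map <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- chartr_map[chars]
  if (anyNA(codes)) stop("sequence contains non-A/C/G/T/N characters")
  unname(codes)
}

#' Score a sequence against a PWM
#'
#' Scans both strands at every offset, reporting the best hit and all hits
#' scoring at least `threshold` times the maximum attainable score.
#' Minus-strand hits are reported at their forward-strand offset. Ties for
#' the best hit are broken by smaller offset, then `+` strand.
#'
#' @param sequence DNA string (A/C/G/T/N, case-insensitive).
#' @param pwm A [pwm()] object.
#' @param threshold Hit threshold as a fraction of the maximum attainable
#'   score (default 0.8).
#' @return List with `best` (one-row data.frame `offset`, `strand`,
#'   `score`), `hits` (all above-threshold hits, ordered by offset),
#'   `max_score` and `threshold_score`.
#' @export
pwm_score <- function(sequence, pwm, threshold = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  L <- ncol(pwm$matrix)
  codes <- seq_codes(sequence)
  n <- length(codes)
  if (n < L) stop("sequence shorter than the motif (", L, " bp)")
  fwd <- pwm_bits(pwm)
  rev <- fwd[c(4:1, 5), rev(seq_len(L)), drop = FALSE]  # revcomp matrix
  offs <- 0:(n - L)
  score_strand <- function(S) {
    sc <- numeric(length(offs))
    for (j in seq_len(L)) sc <- sc + S[codes[offs + j], j]
    sc
  }
  sp <- score_strand(fwd)
  sm <- score_strand(rev)
  max_score <- sum(apply(fwd[1:4, , drop = FALSE], 2, max))
  thr <- threshold * max_score
  hits <- rbind(
    data.frame(offset = offs, strand = "+", score = sp),
    data.frame(offset = offs, strand = "-", score = sm))
  hits <- hits[order(hits$offset, hits$strand), ]
  best <- hits[order(-hits$score, hits$offset, hits$strand), ][1, ]
  rownames(best) <- NULL
  above <- hits[hits$score >= thr, , drop = FALSE]
  rownames(above) <- NULL
  list(best = best, hits = above, max_score = max_score,
       threshold_score = thr)
}

#' Rank PWMs over candidate-enhancer sequences
#'
#' Scores every PWM against every candidate sequence and tabulates, per
#' PWM, the best score anywhere and the number of above-threshold hits
#' across all candidates; sorted by best score descending, ties broken by
#' motif name.
#'
#' @param sequences Named character vector (or list) of candidate
#'   sequences.
#' @param pwms List of `pwm` objects.
#' @param threshold Hit threshold fraction (see [pwm_score()]).
#' @return Data.frame `motif`, `best_score`, `best_sequence`, `n_hits`,
#'   `max_score`.
#' @export
rank_motifs <- function(sequences, pwms, threshold = 0.8) {
  stopifnot(length(sequences) >= 1, length(pwms) >= 1)
  sequences <- unlist(sequences)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("candidate_", seq_along(sequences))
  }
  rows <- lapply(pwms, function(p) {
    best <- -Inf; best_seq <- NA_character_; nhits <- 0L
    for (nm in names(sequences)) {
      s <- sequences[[nm]]
      if (nchar(s) < ncol(p$matrix)) next
      r <- pwm_score(s, p, threshold = threshold)
      nhits <- nhits + nrow(r$hits)
      if (r$best$score > best) {
        best <- r$best$score; best_seq <- nm
      }
    }
    data.frame(motif = p$name, best_score = best, best_sequence = best_seq,
               n_hits = nhits,
               max_score = sum(apply(pwm_bits(p)[1:4, , drop = FALSE],
                                     2, max)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$best_score, out$motif), ]
  rownames(out) <- NULL
  out
}

#' Extract candidate sequences from a genome
#'
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param candidates BED-like data.frame (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return Named character vector of sequences
#'   (`<chrom>:<start>-<end>`).
#' @export
candidate_sequences <- function(genome, candidates) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (nrow(candidates) == 0) return(stats::setNames(character(0), character(0)))
  seqs <- vapply(seq_len(nrow(candidates)), function(i) {
    as.character(Biostrings::subseq(genome[[candidates$chrom[i]]],
                                    start = candidates$start[i] + 1L,
                                    end = candidates$end[i]))
  }, character(1))
  stats::setNames(seqs, paste0(candidates$chrom, ":", candidates$start,
                               "-", candidates$end))
}
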