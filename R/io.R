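#' Read and write BED-like interval files
#'
#' Plain-text tab-separated intervals, 0-based half-open, no header.
#' `read_bed` names the first columns `chrom`, `start`, `end`, `name`,
#' `score`, `strand` as far as present; `write_bed` writes whatever
#' columns the data.frame holds, sorted by (chrom, start) for
#' diffability.
#'
#' @param path File path.
#' @param df Data.frame with at least `chrom`, `start`, `end`.
#' @return `read_bed`: a data.frame. `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  std <- c("chrom", "start", "end", "name", "score", "strand")
  names(df)[seq_len(min(ncol(df), length(std)))] <-
    std[seq_len(min(ncol(df), length(std)))]
  if (ncol(df) < 3) stop("BED file ", path, " has fewer than 3 columns")
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1]
    stop("corrupt BED input ", path, ": end <= start at line ", bad)
  }
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write bedGraph signal tracks
#'
#' Four-column (`chrom`, `start`, `end`, `value`) step functions, 0-based
#' half-open, written sorted by (chrom, start).
#'
#' @param path File path.
#' @param df Data.frame with `chrom`, `start`, `end`, `value`.
#' @return `read_bedgraph`: a data.frame. `write_bedgraph`: `path`,
#'   invisibly.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 4) stop("bedGraph file ", path, " has fewer than 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  df
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  df <- df[order(df$chrom, df$start),
           c("chrom", "start", "end", "value")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write fragment-level read tables
#'
#' Tab-separated with header: `sample`, `chrom`, `fragment_index`,
#' `count`.
#'
#' @param path File path.
#' @param reads Read table data.frame.
#' @return `read_reads_tsv`: a data.frame. `write_reads_tsv`: `path`,
#'   invisibly.
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "fragment_index", "count")
  if (!all(need %in% names(df))) {
    stop("read table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_reads_tsv
#' @export
write_reads_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
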