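#' Restriction enzymes
#'
#' Construct a restriction enzyme from the built-in catalogue or from an
#' explicit recognition site. The catalogue covers the enzymes used in
#' typical two-enzyme 4C designs: DpnII (GATC) for the primary digestion
#' and Csp6I (GTAC) for the secondary digestion, plus a few common
#' alternatives.
#'
#' @param name Enzyme name. If `site` is `NULL` the name must be present in
#'   the built-in catalogue (see [enzyme_catalogue()]).
#' @param site Optional recognition site as an IUPAC DNA string; overrides
#'   the catalogue.
#' @return An object of class `restriction_enzyme` with fields `name` and
#'   `site`.
#' @examples
#' restriction_enzyme("DpnII")
#' restriction_enzyme("FakeI", site = "CANNTG")
#' @export
restriction_enzyme <- function(name, site = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(site)) {
    cat <- enzyme_catalogue()
    if (!name %in% names(cat)) {
      stop("unknown enzyme '", name, "'; supply `site` or use one of: ",
           paste(names(cat), collapse = ", "))
    }
    site <- cat[[name]]
  }
  site <- toupper(site)
  if (!nzchar(site)) stop("recognition site must be non-empty")
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  bad <- setdiff(strsplit(site, "")[[1]], iupac)
  if (length(bad)) {
    stop("recognition site contains non-IUPAC characters: ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(name = name, site = site), class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @export
enzyme_catalogue <- function() {
  c(DpnII = "GATC", MboI = "GATC", Csp6I = "GTAC", NlaIII = "CATG",
    HindIII = "AAGCTT", EcoRI = "GAATTC", BglII = "AGATCT")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat("<restriction_enzyme>", x$name, "cuts at", x$site, "\n")
  invisible(x)
}

as_enzyme <- function(enzyme) {
  if (inherits(enzyme, "restriction_enzyme")) return(enzyme)
  restriction_enzyme(enzyme)
}

#' In-silico digestion of a DNA sequence
#'
#' Cuts a sequence at the first base of every occurrence of the enzyme's
#' recognition site (blunt-cut abstraction; enzyme overhangs are ignored,
#' which is immaterial at the 2 kb windowing resolution used downstream).
#' IUPAC degeneracy in the recognition site is honoured; `N` in the
#' *sequence* never produces a cut. All coordinates are 0-based half-open.
#'
#' @param sequence A DNA string (`character` or [Biostrings::DNAString]),
#'   alphabet A/C/G/T/N.
#' @param enzyme A `restriction_enzyme` or an enzyme name.
#' @return A `data.frame` with columns `start`, `end` (0-based half-open)
#'   and `index` (1-based ordinal along the sequence). Fragments tile
#'   `[0, nchar(sequence))` exactly. A sequence with no site occurrence
#'   (including a site longer than the sequence) yields a single fragment.
#' @examples
#' digest_sequence("AAGATCAAGATCAA", "DpnII")
#' @export
digest_sequence <- function(sequence, enzyme) {
  enzyme <- as_enzyme(enzyme)
  if (inherits(sequence, "DNAString")) {
    dna <- sequence
  } else {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    dna <- Biostrings::DNAString(toupper(sequence))
  }
  len <- length(dna)
  if (len == 0L) stop("cannot digest an empty sequence")
  cuts <- integer(0)
  if (nchar(enzyme$site) <= len) {
    hits <- Biostrings::matchPattern(enzyme$site, dna, fixed = "subject")
    cuts <- BiocGenerics::start(hits) - 1L  # 0-based cut positions
  }
  bounds <- unique(c(0L, cuts[cuts > 0 & cuts < len], as.integer(len)))
  bounds <- sort(bounds)
  n <- length(bounds) - 1L
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             index = seq_len(n))
}

#' Build a genome-wide restriction-fragment map
#'
#' Applies [digest_sequence()] to every chromosome of a genome. Fragment
#' maps are the coordinate backbone for read assignment and viewpoint
#' resolution.
#'
#' @param genome A named [Biostrings::DNAStringSet] or a path to a FASTA
#'   file. Chromosome names must be unique and sequences non-empty.
#' @param enzyme A `restriction_enzyme` or enzyme name.
#' @return An object of class `fragment_map`: a list with `chrom_sizes`
#'   (named integer vector), `fragments` (data.frame `chrom`, `start`,
#'   `end`, `index`) and `enzyme`.
#' @export
build_fragment_map <- function(genome, enzyme) {
  enzyme <- as_enzyme(enzyme)
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  nm <- names(genome)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    stop("all chromosomes must be named")
  }
  if (anyDuplicated(nm)) stop("duplicate chromosome names in genome")
  if (any(Biostrings::width(genome) == 0L)) stop("empty chromosome in genome")
  frags <- lapply(nm, function(chr) {
    f <- digest_sequence(genome[[chr]], enzyme)
    f$chrom <- chr
    f[, c("chrom", "start", "end", "index")]
  })
  structure(
    list(chrom_sizes = stats::setNames(Biostrings::width(genome), nm),
         fragments = do.call(rbind, frags),
         enzyme = enzyme),
    class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("<fragment_map>", length(x$chrom_sizes), "chromosomes,",
      nrow(x$fragments), "fragments,", x$enzyme$name,
      paste0("(", x$enzyme$site, ")"), "\n")
  invisible(x)
}

#' Resolve a genomic position to its restriction fragment
#'
#' Locates the fragment containing a (chrom, position) pair under the
#' half-open containment convention, yielding the viewpoint anchor used by
#' the quantification stage. The promoter primer coordinates of a real
#' experiment reduce to such a pair.
#'
#' @param map A `fragment_map`.
#' @param chrom Chromosome name.
#' @param position 0-based position, `0 <= position < chrom length`.
#' @param name Optional viewpoint label (e.g. the gene whose promoter it is).
#' @return An object of class `viewpoint` with fields `name`, `chrom`,
#'   `position`, `fragment_index`.
#' @export
resolve_viewpoint <- function(map, chrom, position, name = chrom) {
  stopifnot(inherits(map, "fragment_map"))
  if (!chrom %in% names(map$chrom_sizes)) {
    stop("chromosome '", chrom, "' not in fragment map")
  }
  len <- map$chrom_sizes[[chrom]]
  if (position < 0 || position >= len) {
    stop("position ", position, " out of bounds for ", chrom,
         " (length ", len, ")")
  }
  f <- map$fragments[map$fragments$chrom == chrom, ]
  idx <- findInterval(position, f$start)
  stopifnot(f$start[idx] <= position, position < f$end[idx])
  structure(list(name = name, chrom = chrom, position = as.integer(position),
                 fragment_index = f$index[idx]),
            class = "viewpoint")
}

#' @export
print.viewpoint <- function(x, ...) {
  cat("<viewpoint>", x$name, paste0(x$chrom, ":", x$position),
      "fragment", x$fragment_index, "\n")
  invisible(x)
}

#' Export a fragment map as 4-column BED
#'
#' @param map A `fragment_map`.
#' @param path Output path. BED is 0-based half-open; the name column is
#'   the fragment index.
#' @return `path`, invisibly.
#' @export
export_fragment_bed <- function(map, path) {
  stopifnot(inherits(map, "fragment_map"))
  f <- map$fragments
  f <- f[order(match(f$chrom, names(map$chrom_sizes)), f$start), ]
  utils::write.table(f[, c("chrom", "start", "end", "index")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
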