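#' Simulate a genome with a guaranteed restriction-site density
#'
#' Draws an i.i.d. random genome (which already carries recognition sites
#' at roughly `1/4^k` density for a site of length `k`) and additionally
#' forces a recognition site every `site_spacing` bp so no restriction
#' fragment can exceed `site_spacing + site length` (5 kb at defaults).
#' A consensus E-box (`CAGCTG`) is written at every planted enhancer
#' summit so motif scanning has a recoverable signal.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named [Biostrings::DNAStringSet]) and
#'   `fmap` (the [build_fragment_map()] of that genome). Deterministic for
#'   a fixed `config$seed`.
#' @export
make_genome <- function(config) {
  config <- validate_sim_config(config)
  enzyme <- as_enzyme(config$enzyme)
  site <- utf8ToInt(enzyme$site)
  if (any(site > 127L) || grepl("[^ACGT]", enzyme$site)) {
    stop("simulated genomes require a literal A/C/G/T recognition site")
  }
  spacing <- config$site_spacing
  bases <- c(65L, 67L, 71L, 84L)  # A C G T
  set.seed(config$seed)
  seqs <- lapply(names(config$chrom_sizes), function(chr) {
    len <- as.integer(config$chrom_sizes[[chr]])
    if (len < 2L * spacing) {
      stop("chromosome ", chr, " shorter than two forced sites (",
           2L * spacing, " bp)")
    }
    codes <- sample(bases, len, replace = TRUE)
    for (pe in config$planted) {
      if (pe$chrom == chr) {
        ebox <- utf8ToInt("CAGCTG")
        # offset from the summit so a forced site at the summit survives
        at <- min(max(pe$summit + 10L, 0L), len - length(ebox))
        codes[at + seq_along(ebox)] <- ebox
      }
    }
    # forced sites are written last: the <= 5 kb fragment cap must hold
    forced <- seq.int(spacing, len - length(site), by = spacing)
    for (p in forced) codes[p + seq_along(site)] <- site
    intToUtf8(codes)
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(config$chrom_sizes)
  fmap <- build_fragment_map(genome, enzyme)
  widths <- fmap$fragments$end - fmap$fragments$start
  stopifnot(all(widths <= spacing + nchar(enzyme$site)))
  list(genome = genome, fmap = fmap)
}
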