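#' Planted enhancer specification
#'
#' Describes one enhancer contact planted by the simulator: a summit
#' position, a footprint width over which viewpoint-contact probability is
#' multiplied, and a per-condition multiplicative effect. An effect of 1
#' means background contact frequency; condition-specific enhancers carry
#' effect 1 in one condition and > 1 in the other.
#'
#' @param chrom Chromosome of the enhancer.
#' @param summit Summit position (bp, 0-based).
#' @param width Footprint width in bp over which the effect applies
#'   (centred on the summit).
#' @param effect Named numeric vector, condition -> multiplicative contact
#'   effect, all `>= 1`.
#' @return A `planted_enhancer` list.
#' @export
planted_enhancer <- function(chrom, summit, width = 2000,
                             effect = c(quadriceps = 1, soleus = 8)) {
  stopifnot(is.numeric(summit), summit >= 0, width > 0,
            is.numeric(effect), !is.null(names(effect)), all(effect >= 1))
  structure(list(chrom = chrom, summit = as.integer(summit),
                 width = as.integer(width), effect = effect),
            class = "planted_enhancer")
}

default_planted <- function(viewpoint_chrom = "chr1", viewpoint_pos = 3e6,
                            conditions = c("quadriceps", "soleus")) {
  offsets <- c(4e5, -8e5, 1.2e6, -1.6e6, 2.0e6)
  lapply(offsets, function(off) {
    eff <- stats::setNames(c(1, 8), conditions)
    planted_enhancer(viewpoint_chrom, viewpoint_pos + off, width = 2000,
                     effect = eff)
  })
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic 4C experiment. Defaults describe a
#' compact but fully featured study: a 7.6 Mb three-chromosome genome
#' digested with DpnII, one promoter viewpoint in the middle of the largest
#' chromosome, power-law contact decay, a 45% cis share (just above the 40%
#' quality gate), 10% artifact reads (undigested + self-ligated), five
#' planted enhancers with an 8-fold contact effect specific to one of two
#' muscle conditions, and two replicates per condition.
#'
#' @param seed Integer seed; every emitted artifact is deterministic in it.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp). The
#'   first chromosome hosts the viewpoint by default.
#' @param enzyme Enzyme name for the primary digestion.
#' @param viewpoint List with `chrom` and `position`.
#' @param n_reads Reads per sample (exact total emitted).
#' @param decay_alpha,decay_d0 Parameters of the cis contact decay
#'   `P(fragment) proportional to (1 + d/d0)^(-alpha)` with `d` the
#'   fragment-midpoint-to-viewpoint distance in bp.
#' @param cis_fraction Expected share of reads on the viewpoint chromosome
#'   (artifact reads included; they sit on the viewpoint fragment).
#' @param invalid_fraction Expected share of artifact reads (undigested
#'   viewpoint fragment + self-ligated neighbours); must not exceed
#'   `cis_fraction`.
#' @param planted List of [planted_enhancer()] objects.
#' @param conditions Character vector of condition labels (two for the
#'   standard design).
#' @param replicates Replicates per condition.
#' @param noise_dispersion Gamma overdispersion of per-fragment replicate
#'   noise (variance of a mean-1 Gamma multiplier); 0 disables it.
#' @param site_spacing Spacing of forced recognition sites in the simulated
#'   genome (bp); guarantees no fragment exceeds `site_spacing + site
#'   length` (5 kb cap at the default 4 kb spacing).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 6e6, chr2 = 8e5, chr3 = 8e5),
                       enzyme = "DpnII",
                       viewpoint = list(chrom = "chr1", position = 3e6),
                       n_reads = 5e5,
                       decay_alpha = 1.0,
                       decay_d0 = 1e4,
                       cis_fraction = 0.45,
                       invalid_fraction = 0.10,
                       planted = NULL,
                       conditions = c("quadriceps", "soleus"),
                       replicates = 2L,
                       noise_dispersion = 0.05,
                       site_spacing = 4000L) {
  if (is.null(planted)) {
    planted <- default_planted(viewpoint$chrom, viewpoint$position, conditions)
  }
  cfg <- structure(
    list(seed = as.integer(seed), chrom_sizes = chrom_sizes, enzyme = enzyme,
         viewpoint = viewpoint, n_reads = n_reads, decay_alpha = decay_alpha,
         decay_d0 = decay_d0, cis_fraction = cis_fraction,
         invalid_fraction = invalid_fraction, planted = planted,
         conditions = conditions, replicates = as.integer(replicates),
         noise_dispersion = noise_dispersion,
         site_spacing = as.integer(site_spacing)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    stopifnot(length(seed) == 1L, !is.na(seed))
    stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) >= 1,
              !is.null(names(chrom_sizes)), all(chrom_sizes > 0))
    stopifnot(viewpoint$chrom %in% names(chrom_sizes),
              viewpoint$position >= 0,
              viewpoint$position < chrom_sizes[[viewpoint$chrom]])
    stopifnot(n_reads > 0)
    stopifnot(decay_alpha > 0, decay_d0 > 0)
    stopifnot(cis_fraction >= 0, cis_fraction <= 1,
              invalid_fraction >= 0, invalid_fraction <= 1,
              invalid_fraction <= cis_fraction)
    stopifnot(length(conditions) >= 1, !anyDuplicated(conditions))
    stopifnot(replicates >= 1)
    stopifnot(noise_dispersion >= 0)
    stopifnot(site_spacing > 0)
    for (p in planted) {
      stopifnot(inherits(p, "planted_enhancer"),
                p$chrom %in% names(chrom_sizes),
                p$summit < chrom_sizes[[p$chrom]],
                all(conditions %in% names(p$effect)))
    }
  })
  cfg
}

# Deterministic per-sample RNG stream, kept below 2^31.
sample_seed <- function(cfg, condition, replicate) {
  ci <- match(condition, cfg$conditions)
  if (is.na(ci)) stop("unknown condition '", condition, "'")
  (abs(cfg$seed) * 613L + ci * 97L + as.integer(replicate)) %% .Machine$integer.max
}
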