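#' Build an experiment manifest
#'
#' Fully crosses viewpoints, conditions and replicates into the sample
#' sheet of a 4C experiment (e.g. 4 promoter viewpoints x 2 muscles x 2
#' replicates = 16 libraries), in deterministic (viewpoint, condition,
#' replicate) order.
#'
#' @param viewpoints Character vector of viewpoint names.
#' @param conditions Character vector of condition names.
#' @param replicates Number of replicates, or a vector of replicate ids.
#' @return An `experiment_manifest` data.frame with columns `viewpoint`,
#'   `condition`, `replicate`, `sample` and attribute `n_samples`.
#' @export
build_manifest <- function(viewpoints, conditions, replicates) {
  stopifnot(length(viewpoints) >= 1, length(conditions) >= 1)
  if (length(replicates) == 1L && is.numeric(replicates)) {
    replicates <- seq_len(replicates)
  }
  stopifnot(length(replicates) >= 1)
  if (anyDuplicated(viewpoints)) stop("duplicate viewpoint names")
  if (anyDuplicated(conditions)) stop("duplicate condition names")
  if (anyDuplicated(replicates)) stop("duplicate replicate ids")
  grid <- expand.grid(replicate = replicates, condition = conditions,
                      viewpoint = viewpoints, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("viewpoint", "condition", "replicate")]
  grid$sample <- paste(grid$viewpoint, grid$condition,
                       paste0("rep", grid$replicate), sep = "_")
  stopifnot(!anyDuplicated(grid$sample))
  structure(grid, n_samples = nrow(grid),
            class = c("experiment_manifest", "data.frame"))
}

pipeline_defaults <- list(
  window_size = 2000,     # interaction-calling window (bp)
  bin_size = 1e6,         # profile bin (bp)
  alpha = 0.05,           # adjusted p-value threshold
  lfc_min = 1.0,          # SDIS |log2FC| threshold
  cis_gate = 0.40,        # cis/overall QC gate (strict >)
  corr_gate = 0.4,        # replicate Pearson QC gate (strict >)
  width_cap = 1000,       # candidate enhancer width cap (bp)
  min_overlap = 1,        # peak overlap predicate (bp)   # artifact-default
  exclusion = 1e4,        # viewpoint-proximal radius (bp) # artifact-default
  seed = 1L)

#' Pipeline configuration
#'
#' All thresholds of the analysis in one validated list. Defaults are the
#' standard printed thresholds of the method (2 kb windows, 1 Mb bins,
#' adjusted p < 0.05, |log2FC| > 1, cis ratio > 40%, replicate r > 0.4,
#' candidate width <= 1000 bp); `min_overlap` and `exclusion` are this
#' package's own defaults for knobs the method leaves unstated. Unknown
#' keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(pipeline_defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(pipeline_defaults, over)
  with(cfg, {
    stopifnot(window_size > 0, bin_size > 0, alpha > 0, alpha < 1,
              lfc_min >= 0, cis_gate > 0, corr_gate > 0, width_cap > 0,
              min_overlap >= 1, exclusion >= 0)
  })
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' Round-trips a `pipeline_config` through JSON unchanged.
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
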