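#' Default analysis configuration
#'
#' The defaults are the parameters used throughout the study design this
#' package implements: cells under 200 UMIs are discarded, the top 425
#' variable genes feed a 40-PC embedding, clustering runs Louvain on a
#' k = 20 KNN graph, single-cell data are log10-transformed and bulk data
#' log2-transformed with an expression floor of 3, differential calls use
#' 5% FDR with a minimal twofold change, and training genes are called at
#' 3 SDs above the fitted null mean.
#'
#' @return named list of configuration values (class `analysis_config`).
#' @export
default_config <- function() {
  structure(list(
    min_cell_umi = 200L,
    n_variable_genes = 425L,
    n_pcs = 40L,
    knn_k = 20L,
    louvain_resolution = 1.0,
    sc_log_base = 10,
    bulk_log_base = 2,
    bulk_floor = 3,
    fdr_q = 0.05,
    min_fold = 2,
    sd_multiplier = 3,
    rng_seed = 1L,
    exclusion_patterns = c("Rps", "Rpl", "Mrps", "Mrpl"),
    cell_cycle_genes = character()
  ), class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' Keys absent from the file take the [default_config()] values. Unknown keys
#' are fatal (typo guard), as are out-of-range values.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param quiet suppress the resolved-config echo.
#' @return `analysis_config` list.
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  cfg <- validate_config(cfg)
  if (!quiet) {
    message("resolved config:")
    for (k in names(cfg)) message("  ", k, ": ", paste(format(cfg[[k]]), collapse = ", "))
  }
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  chk_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop("config: '", key, "' must be a single positive number (got ",
           paste(format(cfg[[key]]), collapse = ","), ")")
    }
  }
  for (key in c("min_cell_umi", "n_variable_genes", "n_pcs", "knn_k",
                "louvain_resolution", "bulk_floor", "sd_multiplier")) {
    chk_pos(key)
  }
  if (!is.numeric(cfg$fdr_q) || cfg$fdr_q <= 0 || cfg$fdr_q >= 1) {
    stop("config: 'fdr_q' must lie strictly in (0, 1)")
  }
  if (!is.numeric(cfg$min_fold) || cfg$min_fold < 1) {
    stop("config: 'min_fold' must be >= 1")
  }
  if (cfg$sc_log_base != 10) stop("config: 'sc_log_base' is fixed at 10")
  if (cfg$bulk_log_base != 2) stop("config: 'bulk_log_base' is fixed at 2")
  for (key in c("min_cell_umi", "n_variable_genes", "n_pcs", "knn_k", "rng_seed")) {
    cfg[[key]] <- as.integer(cfg[[key]])
  }
  cfg$exclusion_patterns <- as.character(cfg$exclusion_patterns)
  cfg$cell_cycle_genes <- as.character(cfg$cell_cycle_genes)
  structure(cfg, class = "analysis_config")
}
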