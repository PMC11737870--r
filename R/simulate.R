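## Synthetic data generators. These define the study conditions every
## downstream stage is tested against: a two-condition splenic CD11b+
## scRNA-seq experiment (768 cells per condition, 6 cell types, a
## STAT1-style training program restricted to trained classical monocytes)
## and a bulk vaccination time course over days 3/14/30/45/60 with planted
## training-responsive genes.

.sc_program_genes <- c(
  "Gbp2", "Gbp3", "Gbp4", "Gbp5", "Cxcl9", "Cxcl10", "Irg1", "Ly6a", "Stat1",
  "Irf1", "Ifit1", "Ifit3", "Ifitm3", "Socs3", "Tap1", "Psmb8", "Psmb9",
  "Igtp", "Iigp1", "Isg15", "Usp18", "Rsad2", "Oasl2", "Bst2", "Zbp1",
  "Irf7", "Cd274", "Il18bp", "Serpina3g", "Ifi47")

.sc_ribo_genes <- c(
  "Rpl3", "Rpl4", "Rpl5", "Rpl6", "Rpl7", "Rpl8", "Rpl9", "Rpl10", "Rpl11",
  "Rpl13", "Rpl13a", "Rpl14", "Rpl15", "Rpl18", "Rpl19", "Rps2", "Rps3",
  "Rps4x", "Rps5", "Rps6", "Rps7", "Rps8", "Rps9", "Rps10", "Rps11", "Rps12",
  "Rps14", "Rps15", "Rps16", "Rps18", "Mrpl12", "Mrps6")

#' Specification for a synthetic single-cell experiment
#'
#' Defaults emulate the scale and structure of a two-condition (control vs
#' BCG-trained) sort of splenic CD11b+ cells: 768 cells per condition, six
#' cell types, log-normal library sizes with median 1474 UMIs, gamma-Poisson
#' counts, per-type marker genes, and a training gene program induced only in
#' trained cells of the target type (classical monocytes).
#'
#' @param n_cells_per_condition cells per condition (default 768).
#' @param cell_type_proportions named probabilities, must sum to 1.
#' @param n_genes total genes simulated.
#' @param markers_per_type planted marker genes per cell type; the first four
#'   per type carry the symbols in [default_markers()] so annotation works on
#'   simulated data.
#' @param marker_log_fold log2 fold elevation of a marker in its own type.
#' @param training_program_genes number of training-program genes (the first
#'   30 carry interferon-response symbols such as Gbp2, Cxcl9, Ly6a, Irg1).
#' @param training_log_fold log2 fold induction of program genes in trained
#'   cells of the target types.
#' @param training_target_types types carrying the program when trained.
#' @param libsize_log_mean,libsize_log_sd log-normal library-size parameters
#'   (natural log). Defaults give median total 1474 UMIs and ~1.5% of cells
#'   below the 200-UMI QC cut.
#' @param baseline_shape,baseline_rate gamma parameters for per-gene relative
#'   expression.
#' @param nb_size gamma-Poisson (negative binomial) size; smaller = more
#'   overdispersion.
#' @param rng_seed integer seed; the whole draw is reproducible from it.
#' @return list of class `sc_sim_spec`.
#' @export
sc_sim_spec <- function(n_cells_per_condition = 768L,
                        cell_type_proportions = c(CM = 0.30, NCM = 0.20, cDC2 = 0.15,
                                                  mcDC2 = 0.12, Neutrophil = 0.13, NK = 0.10),
                        n_genes = 2000L,
                        markers_per_type = 8L,
                        marker_log_fold = 3,
                        training_program_genes = 30L,
                        training_log_fold = 2,
                        training_target_types = "CM",
                        libsize_log_mean = log(1474),
                        libsize_log_sd = 0.9,
                        baseline_shape = 0.4,
                        baseline_rate = 0.4,
                        nb_size = 2,
                        rng_seed = 1L) {
  spec <- structure(as.list(environment()), class = "sc_sim_spec")
  if (abs(sum(spec$cell_type_proportions) - 1) > 1e-9) {
    stop("cell_type_proportions must sum to 1 (got ", sum(spec$cell_type_proportions), ")")
  }
  if (is.null(names(spec$cell_type_proportions))) stop("cell_type_proportions must be named")
  if (any(unlist(spec[c("n_cells_per_condition", "n_genes", "markers_per_type",
                        "training_program_genes")]) <= 0)) {
    stop("all counts in the spec must be positive")
  }
  if (!all(spec$training_target_types %in% names(spec$cell_type_proportions))) {
    stop("training_target_types must name simulated cell types")
  }
  spec
}

#' Simulate a two-condition single-cell UMI count matrix
#'
#' Counts are gamma-Poisson per gene x cell with per-cell library scaling.
#' Marker genes are elevated `2^marker_log_fold`-fold in their own type;
#' training-program genes are elevated `2^training_log_fold`-fold only in
#' trained-condition cells of the target types. Gene symbols include real
#' ribosomal and cell-cycle genes so the preprocessing exclusions have
#' something to act on.
#'
#' @param spec an [sc_sim_spec()].
#' @return list with `counts` (integer matrix, genes x cells, `layer_tag`
#'   "umi"), `metadata` (data.frame: column_id, condition, replicate,
#'   population), and `truth` (list: `cell_type_of` named vector,
#'   `program_genes`, `marker_genes_of` named list).
#' @export
simulate_sc_counts <- function(spec = sc_sim_spec()) {
  stopifnot(inherits(spec, "sc_sim_spec"))
  set.seed(spec$rng_seed)
  types <- names(spec$cell_type_proportions)
  n_types <- length(types)

  ## gene universe: per-type markers, training program, ribosomal,
  ## cell-cycle, then anonymous filler
  marker_genes_of <- list()
  marker_table <- default_markers()
  for (ty in types) {
    real <- marker_table$gene[marker_table$type == ty]
    k <- spec$markers_per_type
    nm <- if (length(real) >= k) real[seq_len(k)] else {
      c(real, sprintf("%s.m%d", ty, seq(length(real) + 1L, k)))
    }
    marker_genes_of[[ty]] <- nm
  }
  program <- if (spec$training_program_genes <= length(.sc_program_genes)) {
    .sc_program_genes[seq_len(spec$training_program_genes)]
  } else {
    c(.sc_program_genes,
      sprintf("Prog%03d", seq_len(spec$training_program_genes - length(.sc_program_genes))))
  }
  cc <- default_cell_cycle_genes()
  named <- unique(c(unlist(marker_genes_of), program, .sc_ribo_genes, cc))
  if (spec$n_genes <= length(named)) stop("n_genes too small for the named gene classes")
  genes <- c(named, sprintf("Gene%04d", seq_len(spec$n_genes - length(named))))

  ## per-gene relative expression; markers/program pinned at a moderate
  ## level, ribosomal genes highly expressed, rest gamma-distributed
  lambda <- rgamma(length(genes), shape = spec$baseline_shape, rate = spec$baseline_rate)
  names(lambda) <- genes
  lambda[unlist(marker_genes_of)] <- 2
  lambda[program] <- 2
  lambda[.sc_ribo_genes] <- rgamma(length(.sc_ribo_genes), shape = 4, rate = 0.5)

  n <- spec$n_cells_per_condition
  conditions <- rep(c("control", "trained"), each = n)
  cell_ids <- sprintf("%s_%04d", ifelse(conditions == "control", "ctrl", "bcg"),
                      c(seq_len(n), seq_len(n)))
  cell_type <- c(sample(types, n, replace = TRUE, prob = spec$cell_type_proportions),
                 sample(types, n, replace = TRUE, prob = spec$cell_type_proportions))
  names(cell_type) <- cell_ids
  libsize <- rlnorm(2L * n, meanlog = spec$libsize_log_mean, sdlog = spec$libsize_log_sd)

  counts <- matrix(0L, nrow = length(genes), ncol = 2L * n,
                   dimnames = list(genes, cell_ids))
  for (ty in types) {
    for (cond in c("control", "trained")) {
      idx <- which(cell_type == ty & conditions == cond)
      if (!length(idx)) next
      lam <- lambda
      lam[marker_genes_of[[ty]]] <- lam[marker_genes_of[[ty]]] * 2^spec$marker_log_fold
      if (cond == "trained" && ty %in% spec$training_target_types) {
        lam[program] <- lam[program] * 2^spec$training_log_fold
      }
      p <- lam / sum(lam)
      mu <- outer(p, libsize[idx])
      counts[, idx] <- matrix(rnbinom(length(mu), mu = mu, size = spec$nb_size),
                              nrow = length(genes))
    }
  }
  attr(counts, "layer_tag") <- "umi"
  metadata <- data.frame(column_id = cell_ids, condition = conditions,
                         replicate = 1L, population = "CD11b+",
                         stringsAsFactors = FALSE)
  truth <- list(cell_type_of = cell_type, program_genes = program,
                marker_genes_of = marker_genes_of)
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Specification for a synthetic bulk vaccination time course
#'
#' Defaults are the parameter-recovery conditions the kinetics statistic is
#' validated under: 5000 genes sampled at days 3, 14, 30, 45 and 60 with 3
#' replicates per condition x timepoint, 5% of genes responsive to training
#' with a sustained profile of 3 log2 units, and additive Gaussian noise of
#' 0.3 log2 units.
#'
#' @param timepoints_days strictly increasing sampling days.
#' @param replicates replicates per condition x timepoint (>= 2).
#' @param n_genes genes simulated.
#' @param responsive_fraction fraction of genes responding to training.
#' @param profile_shapes subset of `c("early_transient","sustained","delayed")`
#'   assigned uniformly to responsive genes. Early-transient profiles peak at
#'   day 14 and return to baseline by day 30; sustained profiles rise by day
#'   14 and stay; delayed profiles rise only from day 30.
#' @param effect_log2 peak effect size (log2 units) of responsive genes.
#' @param noise_sd_log2 SD of additive Gaussian noise on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline distribution.
#' @param rng_seed integer seed.
#' @return list of class `bulk_sim_spec`.
#' @export
bulk_sim_spec <- function(timepoints_days = c(3, 14, 30, 45, 60),
                          replicates = 3L,
                          n_genes = 5000L,
                          responsive_fraction = 0.05,
                          profile_shapes = "sustained",
                          effect_log2 = 3,
                          noise_sd_log2 = 0.3,
                          baseline_log2_mean = 6,
                          baseline_log2_sd = 1.5,
                          rng_seed = 1L) {
  spec <- structure(as.list(environment()), class = "bulk_sim_spec")
  if (any(diff(spec$timepoints_days) <= 0)) stop("timepoints_days must be strictly increasing")
  if (spec$replicates < 2) stop("replicates must be >= 2 (downstream tests need them)")
  if (!all(spec$profile_shapes %in% c("early_transient", "sustained", "delayed"))) {
    stop("unknown profile shape(s): ",
         paste(setdiff(spec$profile_shapes, c("early_transient", "sustained", "delayed")),
               collapse = ", "))
  }
  if (spec$responsive_fraction < 0 || spec$responsive_fraction > 1) {
    stop("responsive_fraction must lie in [0, 1]")
  }
  spec
}

#' Piecewise-linear training-response templates
#'
#' Unit-height templates on the day axis: `early_transient` rises from 0 at
#' day 0 to 1 at day 14 and is back at 0 by day 30; `sustained` rises to 1 at
#' day 14 and stays; `delayed` is flat until day 30 and reaches 1 at day 45.
#'
#' @param shape template name.
#' @param days numeric vector of days.
#' @return numeric vector in `[0, 1]`, same length as `days`.
#' @export
profile_template <- function(shape, days) {
  knots <- switch(shape,
    early_transient = list(x = c(0, 14, 30), y = c(0, 1, 0)),
    sustained       = list(x = c(0, 14),     y = c(0, 1)),
    delayed         = list(x = c(0, 30, 45), y = c(0, 0, 1)),
    stop("unknown profile shape: ", shape))
  stats::approx(knots$x, knots$y, xout = days, rule = 2)$y
}

#' Simulate a bulk training time course
#'
#' Per-sample log2 expression = gene baseline + (responsive genes, trained
#' condition only) effect x profile template + Gaussian noise. Emitted both
#' as the log2 matrix and as rounded linear-scale counts for pipeline-entry
#' testing.
#'
#' @param spec a [bulk_sim_spec()].
#' @return list with `log2` (matrix genes x samples), `counts` (integer
#'   matrix, `round(2^log2 - 1)`), `metadata` (column_id, condition,
#'   timepoint_days, replicate), and `truth` (data.frame gene_id, shape,
#'   effect_log2 for responsive genes).
#' @export
simulate_bulk_timecourse <- function(spec = bulk_sim_spec()) {
  stopifnot(inherits(spec, "bulk_sim_spec"))
  set.seed(spec$rng_seed)
  genes <- sprintf("Gene%05d", seq_len(spec$n_genes))
  md <- expand.grid(replicate = seq_len(spec$replicates),
                    timepoint_days = spec$timepoints_days,
                    condition = c("control", "trained"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md$column_id <- sprintf("%s_d%02d_r%d", md$condition, md$timepoint_days, md$replicate)
  md <- md[, c("column_id", "condition", "timepoint_days", "replicate")]

  baseline <- rnorm(spec$n_genes, spec$baseline_log2_mean, spec$baseline_log2_sd)
  n_resp <- round(spec$responsive_fraction * spec$n_genes)
  responsive <- sort(sample(seq_len(spec$n_genes), n_resp))
  shape_of <- if (n_resp > 0) {
    sample(spec$profile_shapes, n_resp, replace = TRUE)
  } else character()

  log2m <- matrix(baseline, nrow = spec$n_genes, ncol = nrow(md),
                  dimnames = list(genes, md$column_id))
  trained_cols <- which(md$condition == "trained")
  if (n_resp > 0) {
    for (s in unique(shape_of)) {
      tmpl <- profile_template(s, md$timepoint_days[trained_cols])
      rows <- responsive[shape_of == s]
      log2m[rows, trained_cols] <- log2m[rows, trained_cols] +
        spec$effect_log2 * rep(tmpl, each = length(rows))
    }
  }
  log2m <- log2m + matrix(rnorm(length(log2m), 0, spec$noise_sd_log2),
                          nrow = nrow(log2m))
  counts <- round(pmax(2^log2m - 1, 0))
  storage.mode(counts) <- "integer"
  attr(counts, "layer_tag") <- "reads"
  truth <- data.frame(gene_id = genes[responsive],
                      shape = shape_of,
                      effect_log2 = rep(spec$effect_log2, n_resp),
                      stringsAsFactors = FALSE)
  list(log2 = log2m, counts = counts, metadata = md, truth = truth)
}

#' Write a simulated dataset beside its ground truth
#'
#' Convenience writer used by the analysis drivers: matrix (TSV dialect),
#' metadata, and a `truth.tsv` in `dir`.
#'
#' @param sim result of [simulate_sc_counts()] or [simulate_bulk_timecourse()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"), format = "tsv")
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  if (is.data.frame(truth)) {
    utils::write.table(truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(column_id = names(truth$cell_type_of),
                     cell_type = unname(truth$cell_type_of),
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(truth$program_genes, file.path(dir, "program_genes.txt"))
  }
  invisible(dir)
}
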