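#' Prepare a bulk time course
#'
#' Bulk processing mirrors the single-cell normalization: per-sample library
#' factors (total / median of totals), then `log2(x + 1)`, then an expression
#' floor — values below `floor` are set to `floor`. Listed samples are
#' excluded up front (e.g. low-coverage libraries) and the removal recorded.
#'
#' @param counts linear-scale matrix (genes x samples) with dimnames.
#' @param metadata data.frame with `column_id`, `condition`,
#'   `timepoint_days`, `replicate` covering every sample.
#' @param floor minimal log2 expression (default 3; 4 for some datasets).
#' @param exclusions character vector of sample ids to drop, or a named
#'   vector whose names are ids and values are reasons.
#' @return object of class `timecourse`: `values` (floored log2 matrix),
#'   `samples` (metadata aligned to columns), `floor_applied`, `exclusions`
#'   (data.frame column_id, reason).
#' @export
prepare_bulk <- function(counts, metadata, floor = 3, exclusions = character()) {
  if (anyNA(counts)) stop("count matrix contains missing values")
  md <- align_metadata(counts, metadata)
  req <- c("condition", "timepoint_days", "replicate")
  if (!all(req %in% names(md))) {
    stop("metadata must provide columns: ", paste(req, collapse = ", "))
  }
  reasons <- if (is.null(names(exclusions))) {
    stats::setNames(rep("manual exclusion", length(exclusions)), exclusions)
  } else {
    stats::setNames(as.character(exclusions), names(exclusions))
  }
  unknown <- setdiff(names(reasons), colnames(counts))
  if (length(unknown)) stop("exclusions name unknown samples: ", paste(unknown, collapse = ", "))
  keep <- !(colnames(counts) %in% names(reasons))
  counts <- counts[, keep, drop = FALSE]
  md <- md[keep, , drop = FALSE]
  tab <- table(md$condition, md$timepoint_days)
  if (any(tab == 0)) {
    stop("condition x timepoint cell(s) left with zero samples after exclusion")
  }
  totals <- colSums(counts)
  if (any(totals == 0)) stop("zero-total sample(s): ",
                             paste(colnames(counts)[totals == 0], collapse = ", "))
  factors <- totals / stats::median(totals)
  values <- log2(sweep(counts, 2, factors, "/") + 1)
  values <- pmax(values, floor)
  structure(list(values = values, samples = md, floor_applied = floor,
                 exclusions = data.frame(column_id = names(reasons),
                                         reason = unname(reasons),
                                         stringsAsFactors = FALSE)),
            class = "timecourse")
}

#' Average replicates per condition and timepoint
#'
#' Arithmetic mean of the log2 values across replicates, per gene, for every
#' condition x timepoint. Missing values are an error, never silently
#' dropped.
#'
#' @param tc a [prepare_bulk()] `timecourse` object.
#' @return object of class `avg_trajectories`: `mean_log2` (named list,
#'   condition -> genes x timepoints matrix), `timepoints_days`, `conditions`.
#' @export
average_replicates <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  if (anyNA(tc$values)) stop("time course contains missing values; fix or exclude the samples")
  conditions <- unique(tc$samples$condition)
  timepoints <- sort(unique(tc$samples$timepoint_days))
  out <- list()
  for (cond in conditions) {
    m <- matrix(NA_real_, nrow(tc$values), length(timepoints),
                dimnames = list(rownames(tc$values), as.character(timepoints)))
    for (j in seq_along(timepoints)) {
      cols <- tc$samples$column_id[tc$samples$condition == cond &
                                     tc$samples$timepoint_days == timepoints[j]]
      if (length(cols)) m[, j] <- rowMeans(tc$values[, cols, drop = FALSE])
    }
    out[[cond]] <- m
  }
  structure(list(mean_log2 = out, timepoints_days = timepoints,
                 conditions = conditions),
            class = "avg_trajectories")
}

#' Trapezoid weights for integration over observed days
#' @param t strictly increasing numeric vector (days).
#' @return weights w such that `sum(w * y)` is the trapezoid integral of y(t).
#' @keywords internal
trapezoid_weights <- function(t) {
  if (length(t) < 2) stop("need at least 2 timepoints to integrate")
  if (any(diff(t) <= 0)) stop("timepoints must be strictly increasing")
  dt <- diff(t)
  c(dt / 2, 0) + c(0, dt / 2)
}

#' Integral difference between treated and control trajectories
#'
#' The training-gene statistic: per gene, the difference between the
#' time-integrals of the averaged log2 trajectories of the treated and
#' control conditions, computed by the trapezoid rule over the observed days
#' (unequal spacing respected; no extrapolation outside the sampled range).
#' Units are log2 x days.
#'
#' @param avg an [average_replicates()] result.
#' @param treated,control condition names (defaults "trained" / "control").
#' @return named numeric vector `D`, one value per gene.
#' @export
integral_difference <- function(avg, treated = "trained", control = "control") {
  stopifnot(inherits(avg, "avg_trajectories"))
  for (cond in c(treated, control)) {
    if (!cond %in% names(avg$mean_log2)) stop("condition not present: ", cond)
    if (anyNA(avg$mean_log2[[cond]])) {
      stop("condition '", cond, "' is missing timepoints in the integration range")
    }
  }
  w <- trapezoid_weights(avg$timepoints_days)
  drop((avg$mean_log2[[treated]] - avg$mean_log2[[control]]) %*% w)
}

#' Call training-up-regulated genes by the fitted-normal 3-SD rule
#'
#' The integral differences across all genes are treated as draws from an
#' approximately normal null; its mean and SD are fitted by the sample
#' moments (optionally median/MAD), and genes whose D strictly exceeds
#' `mean + sd_multiplier * SD` are called up-regulated due to training.
#'
#' @param D named numeric vector of integral differences.
#' @param sd_multiplier threshold multiplier (default 3).
#' @param robust use median/MAD instead of mean/SD for the null fit.
#' @param call_downregulated also report genes below `mean - k * SD`
#'   (off by default; only up-regulation defines training).
#' @return object of class `training_call`: `D`, `null_mean`, `null_sd`,
#'   `threshold`, `upregulated` (gene ids), optionally `downregulated`.
#' @export
call_training_genes <- function(D, sd_multiplier = 3, robust = FALSE,
                                call_downregulated = FALSE) {
  if (length(D) < 2) stop("need at least 2 genes to fit the null")
  if (robust) {
    null_mean <- stats::median(D)
    null_sd <- stats::mad(D)
  } else {
    null_mean <- mean(D)
    null_sd <- stats::sd(D)
  }
  threshold <- null_mean + sd_multiplier * null_sd
  if (null_sd == 0) {
    warning("degenerate null (SD = 0): no genes called")
    up <- character()
    down <- character()
  } else {
    up <- names(D)[D > threshold]
    down <- names(D)[D < null_mean - sd_multiplier * null_sd]
  }
  structure(list(D = D, null_mean = null_mean, null_sd = null_sd,
                 sd_multiplier = sd_multiplier, threshold = threshold,
                 upregulated = up,
                 downregulated = if (call_downregulated) down else NULL),
            class = "training_call")
}

#' @export
print.training_call <- function(x, ...) {
  cat("training_call: null mean", signif(x$null_mean, 4), ", SD",
      signif(x$null_sd, 4), "; threshold", signif(x$threshold, 4), "\n")
  cat(" ", length(x$upregulated), "of", length(x$D),
      "genes called up-regulated due to training\n")
  invisible(x)
}

#' PCA of bulk samples on z-scored genes
#'
#' Genes are centered and scaled to mean 0 / SD 1 across samples
#' (zero-variance genes dropped with a warning), then the samples are
#' embedded by PCA.
#'
#' @param tc a `timecourse` object or a plain log2 matrix (genes x samples).
#' @param gene_subset optional gene ids to restrict to (e.g. a DEG list).
#' @return an `embedding` (coordinates = samples x PCs).
#' @export
bulk_pca <- function(tc, gene_subset = NULL) {
  values <- if (inherits(tc, "timecourse")) tc$values else tc
  if (ncol(values) < 2) stop("need at least 2 samples")
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(values))
    if (length(missing)) stop("gene_subset not in matrix: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    values <- values[gene_subset, , drop = FALSE]
  }
  sds <- apply(values, 1, stats::sd)
  if (all(sds == 0)) stop("all genes have zero variance")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped before PCA")
    values <- values[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (values - rowMeans(values)) / sds
  pr <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  n_pcs <- ncol(pr$x)
  coords <- pr$x
  load <- pr$rotation
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  structure(list(coordinates = coords, loadings = load,
                 explained_variance = pr$sdev^2 / sum(pr$sdev^2),
                 center = rep(0, nrow(z))),
            class = "embedding")
}
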