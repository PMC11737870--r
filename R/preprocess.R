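#' Cell and gene quality-control filter
#'
#' Removes cells with total UMI count strictly below `min_cell_umi`, then
#' genes with no counts in any retained cell (only genes with at least one
#' UMI detected in at least one cell are kept). Idempotent.
#'
#' @param counts integer count matrix (genes x cells) with dimnames.
#' @param min_cell_umi minimal per-cell total (default 200).
#' @return list with `counts` (filtered matrix) and `report` (class
#'   `qc_report`): cells in/removed, removed ids, per-retained-cell totals
#'   and detected-gene counts, and their medians.
#' @export
qc_filter <- function(counts, min_cell_umi = 200L) {
  counts_in <- validate_count_matrix(counts)
  totals <- colSums(counts_in)
  keep_cells <- totals >= min_cell_umi
  if (!any(keep_cells)) stop("no cells pass QC (all totals < ", min_cell_umi, ")")
  removed_ids <- colnames(counts_in)[!keep_cells]
  kept <- counts_in[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(kept) > 0
  kept <- kept[keep_genes, , drop = FALSE]
  attr(kept, "layer_tag") <- attr(counts, "layer_tag")
  total_umi <- colSums(kept)
  n_genes_detected <- colSums(kept > 0)
  report <- structure(list(
    n_cells_in = ncol(counts_in),
    n_cells_removed = length(removed_ids),
    removed_ids = removed_ids,
    n_genes_removed = sum(!keep_genes),
    total_umi = total_umi,
    n_genes_detected = n_genes_detected,
    median_total_umi = stats::median(total_umi),
    median_genes_per_cell = stats::median(n_genes_detected)
  ), class = "qc_report")
  list(counts = kept, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$n_cells_in, "cells in,", x$n_cells_removed, "removed;",
      x$n_genes_removed, "all-zero genes dropped\n")
  cat("  median total UMI:", x$median_total_umi,
      "| median genes/cell:", x$median_genes_per_cell, "\n")
  invisible(x)
}

#' Median library-size factors
#'
#' Per-cell factor = total UMI count divided by the median of totals across
#' cells, so the median factor is exactly 1. The median of an even number of
#' cells is the mid-mean of the central pair.
#'
#' @param counts QC-filtered count matrix.
#' @return named positive numeric vector, one factor per cell, with the
#'   median total as attribute `median_total`.
#' @export
compute_size_factors <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero-total column(s): ", paste(names(totals)[totals == 0], collapse = ", "),
         " (run qc_filter first)")
  }
  med <- stats::median(totals)
  factors <- totals / med
  attr(factors, "median_total") <- med
  factors
}

#' Size-factor normalization and log10 transform
#'
#' `value = log10(count / factor + 1)`: counts are scaled to the median
#' library size, then log10-transformed with a pseudocount of 1.
#'
#' @param counts count matrix (genes x cells).
#' @param factors size factors from [compute_size_factors()], aligned to the
#'   columns of `counts`.
#' @return numeric matrix with a `transform` attribute recording the
#'   normalization, log base and pseudocount.
#' @export
normalize_log10 <- function(counts, factors) {
  if (length(factors) != ncol(counts) ||
      (!is.null(names(factors)) && !identical(names(factors), colnames(counts)))) {
    stop("size factors are not aligned to the matrix columns")
  }
  if (any(factors <= 0)) stop("size factors must be strictly positive")
  expr <- log10(sweep(counts, 2, factors, "/") + 1)
  attr(expr, "transform") <- list(normalization = "median_size_factor",
                                  log_base = 10, pseudocount = 1)
  expr
}

#' Variable-gene selection by a mean-CV noise model
#'
#' Genes matching the exclusion prefixes (ribosomal by default) or the
#' cell-cycle list are set aside. For the remaining genes the mean and the
#' coefficient of variation (SD/mean) are computed on the de-logged
#' normalized values; the expected log(CV) at a gene's log(mean) is estimated
#' by a rolling median over mean-ordered genes (window `max(25, 1%)` of
#' eligible genes), and the excess-dispersion score is the observed minus the
#' expected log(CV). The top `n` genes by score are selected, ties broken
#' lexicographically by gene id.
#'
#' @param expr matrix from [normalize_log10()].
#' @param n number of variable genes to select (default 425).
#' @param exclusion_patterns gene-symbol prefixes to exclude.
#' @param cell_cycle_genes explicit gene ids to exclude.
#' @return list of class `variable_gene_result`: `selected` (length `n`,
#'   score-descending), `stats` (data.frame gene_id, mean, cv, score),
#'   `excluded_by_class`.
#' @export
select_variable_genes <- function(expr, n = 425L,
                                  exclusion_patterns = c("Rps", "Rpl", "Mrps", "Mrpl"),
                                  cell_cycle_genes = character()) {
  tf <- attr(expr, "transform")
  base <- if (is.null(tf)) 10 else tf$log_base
  pseudo <- if (is.null(tf)) 1 else tf$pseudocount
  linear <- base^expr - pseudo
  genes <- rownames(expr)
  excl <- rep(FALSE, length(genes))
  for (p in exclusion_patterns) excl <- excl | startsWith(genes, p)
  excl <- excl | genes %in% cell_cycle_genes
  excluded_by_class <- genes[excl]

  m <- rowMeans(linear)
  v <- apply(linear, 1, stats::sd)
  cv <- ifelse(m > 0, v / m, NA_real_)
  eligible <- !excl & !is.na(cv) & cv > 0 & m > 0
  n_elig <- sum(eligible)
  if (n > n_elig) {
    stop("requested ", n, " variable genes but only ", n_elig, " are eligible ",
         "(", length(genes), " genes, ", length(excluded_by_class), " class-excluded)")
  }
  idx <- which(eligible)
  ord <- idx[order(m[idx])]
  k <- max(25L, ceiling(0.01 * n_elig))
  if (k %% 2 == 0) k <- k + 1L
  if (k > n_elig) k <- n_elig - (1 - n_elig %% 2)
  logcv <- log(cv[ord])
  expected <- stats::runmed(logcv, k, endrule = "median")
  score <- rep(NA_real_, length(genes))
  names(score) <- genes
  score[ord] <- logcv - expected

  elig_genes <- genes[idx]
  o <- order(-score[elig_genes], elig_genes)
  selected <- elig_genes[o][seq_len(n)]
  structure(list(
    selected = selected,
    stats = data.frame(gene_id = genes, mean = m, cv = cv, score = score[genes],
                       row.names = NULL, stringsAsFactors = FALSE),
    excluded_by_class = excluded_by_class
  ), class = "variable_gene_result")
}
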