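#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; rejecting all genes
#' with `q <= alpha` is equivalent to the BH step-up rule at level `alpha`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene pooled two-sample t-test
#' @return list(statistic, p_value); degenerate genes (zero pooled variance)
#'   get p = 1 when the means agree and p = 0 otherwise.
#' @keywords internal
.gene_ttest <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0))
  }
  ht <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(ht)) {
    if (mean(x) == mean(y)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Two-sided t-test differential expression
#'
#' Per-gene two-sided two-sample t-test (pooled variance by default) between
#' two column groups of a log2 expression matrix, with BH adjustment across
#' genes and an optional minimal-fold filter (`|log2 fold change| >=
#' log2(min_fold)`, the fold change being the group-A minus group-B mean on
#' the log2 scale). Supports pooling samples across populations by simply
#' passing the pooled column sets.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param group_a,group_b column ids (or indices) of the two groups, >= 2 each.
#' @param fdr_q FDR level for the `pass` flag (default 0.05).
#' @param min_fold minimal linear fold change, or `NULL` to disable.
#' @param var_equal pooled-variance t-test (default); `FALSE` gives Welch.
#' @return data.frame of class `deg_result`: gene_id, statistic, p_value,
#'   q_value, log2_fold_change, pass; attributes record the contrast and
#'   thresholds.
#' @export
ttest_deg <- function(expr, group_a, group_b, fdr_q = 0.05, min_fold = NULL,
                      var_equal = TRUE) {
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2) {
    stop("each group needs at least 2 samples (got ", ncol(a), " and ", ncol(b), ")")
  }
  res <- vapply(seq_len(nrow(expr)), function(g) {
    ht <- .gene_ttest(a[g, ], b[g, ], var_equal)
    c(ht$statistic, ht$p_value)
  }, numeric(2))
  statistic <- res[1, ]
  p <- res[2, ]
  q <- bh_adjust(p)
  lfc <- rowMeans(a) - rowMeans(b)
  pass <- q <= fdr_q
  if (!is.null(min_fold)) pass <- pass & abs(lfc) >= log2(min_fold)
  out <- data.frame(gene_id = rownames(expr), statistic = statistic,
                    p_value = p, q_value = q, log2_fold_change = unname(lfc),
                    pass = pass, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- list(group_a = colnames(a), group_b = colnames(b))
  attr(out, "fdr_q") <- fdr_q
  attr(out, "min_fold") <- min_fold
  class(out) <- c("deg_result", "data.frame")
  out
}

#' One-way ANOVA differential expression
#'
#' Per-gene one-way F-test across >= 3 groups with BH adjustment and a fold
#' filter: the maximal pairwise ratio of de-logged group means must reach
#' `min_fold`.
#'
#' @param expr log2 expression matrix (genes x samples).
#' @param groups factor/character of group labels, one per column.
#' @param fdr_q FDR level (default 0.05).
#' @param min_fold minimal max/min group-mean ratio on the linear scale
#'   (default 2), or `NULL` to disable.
#' @return `deg_result` data.frame; `log2_fold_change` holds the log2 of the
#'   maximal pairwise group-mean ratio.
#' @export
anova_deg <- function(expr, groups, fdr_q = 0.05, min_fold = 2) {
  groups <- factor(groups)
  if (length(groups) != ncol(expr)) stop("groups must label every column")
  if (nlevels(groups) < 3) {
    stop("fewer than 3 groups; use ttest_deg() for a two-group contrast")
  }
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  res <- vapply(seq_len(nrow(expr)), function(g) {
    x <- expr[g, ]
    gm <- tapply(x, groups, mean)
    within_var <- tapply(x, groups, stats::var)
    if (all(within_var == 0)) {
      p <- if (max(gm) == min(gm)) 1 else 0
      return(c(if (p == 1) 0 else Inf, p, max(gm) - min(gm)))
    }
    ht <- stats::oneway.test(x ~ groups, var.equal = TRUE)
    c(unname(ht$statistic), ht$p.value, max(gm) - min(gm))
  }, numeric(3))
  p <- res[2, ]
  q <- bh_adjust(p)
  max_lfc <- res[3, ]  # log2 of max pairwise linear-scale mean ratio
  pass <- q <= fdr_q
  if (!is.null(min_fold)) pass <- pass & 2^max_lfc >= min_fold
  out <- data.frame(gene_id = rownames(expr), statistic = res[1, ],
                    p_value = p, q_value = q, log2_fold_change = max_lfc,
                    pass = pass, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- list(groups = levels(groups))
  attr(out, "fdr_q") <- fdr_q
  attr(out, "min_fold") <- min_fold
  class(out) <- c("deg_result", "data.frame")
  out
}

#' Union of DEGs over multiple pairwise contrasts
#'
#' Runs [ttest_deg()] for every listed contrast (BH within each contrast)
#' and returns the union of passing genes, each annotated with the contrasts
#' it passed.
#'
#' @param expr log2 expression matrix.
#' @param contrasts named list; each element a list with `a` and `b` column
#'   sets.
#' @param fdr_q per-contrast FDR level.
#' @param min_fold optional fold filter passed through to [ttest_deg()].
#' @return list with `per_contrast` (named list of `deg_result`) and `union`
#'   (data.frame gene_id, contrasts, n_contrasts).
#' @export
multi_contrast_union <- function(expr, contrasts, fdr_q = 0.05, min_fold = NULL) {
  if (!length(contrasts)) stop("empty contrast list")
  if (is.null(names(contrasts))) {
    names(contrasts) <- paste0("contrast_", seq_along(contrasts))
  }
  per <- lapply(contrasts, function(ct) {
    ttest_deg(expr, ct$a, ct$b, fdr_q = fdr_q, min_fold = min_fold)
  })
  hits <- lapply(per, function(r) r$gene_id[r$pass])
  union_genes <- sort(unique(unlist(hits)))
  which_ct <- vapply(union_genes, function(g) {
    paste(names(hits)[vapply(hits, function(h) g %in% h, logical(1))], collapse = ";")
  }, character(1))
  union <- data.frame(gene_id = union_genes, contrasts = unname(which_ct),
                      n_contrasts = lengths(strsplit(which_ct, ";")),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(per_contrast = per, union = union)
}
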