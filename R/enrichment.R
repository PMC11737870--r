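#' Over-representation analysis against a gene-set collection
#'
#' Hypergeometric upper-tail test of the overlap between a query gene list
#' (typically DEGs or training-called genes) and every set in a collection,
#' both intersected with the expression universe, followed by BH adjustment
#' across sets. The discrete analog of ranked gene-set enrichment for
#' threshold-defined gene lists.
#'
#' @param query character vector of gene ids (deduplicated; intersected with
#'   the universe — an empty intersection is an error).
#' @param universe character vector: all genes the query was drawn from
#'   (e.g. genes surviving the expression floor).
#' @param sets a [gene_set_collection()] or a named list of gene id vectors.
#' @param fdr_q FDR level for the `pass` flag.
#' @return data.frame of class `enrichment_result`, sorted by q then p:
#'   set, overlap, set_size (in-universe), universe_size, query_size,
#'   p_value, q_value, pass, overlap_genes (semicolon-joined).
#' @export
ora <- function(query, universe, sets, fdr_q = 0.05) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (!length(sets)) stop("empty gene-set collection")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (!length(query)) stop("query is empty after intersection with the universe")
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- intersect(query, s)
    k <- length(ov)
    p <- if (length(s) == 0) 1 else {
      stats::phyper(k - 1, length(s), n_u - length(s), n_q, lower.tail = FALSE)
    }
    data.frame(set = nm, overlap = k, set_size = length(s),
               universe_size = n_u, query_size = n_q, p_value = p,
               overlap_genes = paste(ov, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$pass <- out$q_value <= fdr_q
  out <- out[order(out$q_value, out$p_value, out$set), ]
  rownames(out) <- NULL
  out <- out[, c("set", "overlap", "set_size", "universe_size", "query_size",
                 "p_value", "q_value", "pass", "overlap_genes")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}
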