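#' Principal component embedding
#'
#' Gene-centered (not variance-scaled) PCA of cells in the space of the
#' supplied genes, typically the variable genes. Component signs are fixed by
#' making the largest-magnitude loading of each component positive, so the
#' embedding is fully deterministic.
#'
#' @param expr expression matrix (genes x cells), usually restricted to the
#'   variable genes.
#' @param n_pcs number of components to keep.
#' @return list of class `embedding`: `coordinates` (cells x n_pcs),
#'   `loadings` (genes x n_pcs), `explained_variance` (fraction per kept
#'   component), `center` (per-gene means).
#' @export
run_pca <- function(expr, n_pcs = 40L) {
  x <- t(expr)
  if (n_pcs > min(dim(x)) - 1) {
    stop("n_pcs = ", n_pcs, " exceeds min(cells, genes) - 1 = ", min(dim(x)) - 1)
  }
  if (all(apply(x, 2, stats::sd) == 0)) stop("zero variance: constant input matrix")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_pcs)
  coords <- pr$x[, keep, drop = FALSE]
  load <- pr$rotation[, keep, drop = FALSE]
  for (j in keep) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  structure(list(coordinates = coords, loadings = load,
                 explained_variance = (pr$sdev^2 / sum(pr$sdev^2))[keep],
                 center = pr$center),
            class = "embedding")
}

#' K-nearest-neighbour graph in PC space
#'
#' Each cell is linked to its `k` nearest others by Euclidean distance in the
#' embedding; the graph is symmetrized by edge union with unit weights, so
#' every node ends with degree >= k. Distance ties are broken by column
#' (cell) order.
#'
#' @param emb an [run_pca()] embedding, or a cells x dims coordinate matrix.
#' @param k neighbours per cell (default 20); must be < number of cells.
#' @return undirected `igraph` graph with vertex names = cell ids and a
#'   graph attribute `k`.
#' @export
build_knn_graph <- function(emb, k = 20L) {
  coords <- if (inherits(emb, "embedding")) emb$coordinates else as.matrix(emb)
  n <- nrow(coords)
  if (k >= n) stop("k = ", k, " must be smaller than the number of cells (", n, ")")
  d <- as.matrix(stats::dist(coords))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    edges[[i]] <- cbind(i, ord)
  }
  e <- do.call(rbind, edges)
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::V(g)$name <- rownames(coords)
  g <- igraph::set_graph_attr(g, "k", k)
  g
}

#' Louvain community detection
#'
#' Standard Louvain modularity optimization on the KNN graph. The node
#' visitation order inside igraph is shuffled from the seed, so results are
#' reproducible given (graph, resolution, seed).
#'
#' @param graph igraph graph from [build_knn_graph()].
#' @param resolution modularity resolution (default 1).
#' @param seed integer RNG seed.
#' @return list of class `sc_clustering`: `labels` (named integer vector,
#'   one label per cell), `n_clusters`, `modularity`, and `annotation`
#'   fields filled by [annotate_clusters()].
#' @export
louvain_cluster <- function(graph, resolution = 1.0, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  labels <- igraph::membership(comm)
  labels <- stats::setNames(as.integer(labels), names(labels))
  structure(list(labels = labels,
                 n_clusters = length(unique(labels)),
                 modularity = igraph::modularity(graph, labels),
                 annotation_of = NULL, marker_scores = NULL,
                 cell_annotation = NULL),
            class = "sc_clustering")
}

#' @export
print.sc_clustering <- function(x, ...) {
  cat("sc_clustering:", x$n_clusters, "clusters over", length(x$labels),
      "cells; modularity", round(x$modularity, 3), "\n")
  if (!is.null(x$annotation_of)) {
    cat("  annotation:", paste(names(x$annotation_of), x$annotation_of,
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Marker-based cluster annotation
#'
#' For every cluster, the mean expression of each cell type's markers is
#' computed and z-scored across clusters; the cluster is annotated with the
#' argmax type. Ties and all-zero clusters are labelled "ambiguous". With a
#' single cluster the z-score degenerates and the raw mean is used.
#'
#' @param clust an [louvain_cluster()] result.
#' @param expr full expression matrix (genes x cells).
#' @param markers marker table: data.frame with `type` and `gene` columns
#'   (as [default_markers()]) or a named list type -> gene ids.
#' @return the clustering with `annotation_of` (cluster -> type),
#'   `cell_annotation` (cell -> type) and `marker_scores` (clusters x types
#'   z-score matrix) filled in.
#' @export
annotate_clusters <- function(clust, expr, markers = default_markers()) {
  stopifnot(inherits(clust, "sc_clustering"))
  if (is.data.frame(markers)) {
    markers <- split(markers$gene, markers$type)
  }
  markers <- lapply(markers, intersect, rownames(expr))
  present <- vapply(markers, length, 1L) > 0
  if (!any(present)) stop("no marker genes found in the expression matrix")
  markers <- markers[present]
  cells <- intersect(colnames(expr), names(clust$labels))
  if (!length(cells)) stop("clustering labels do not match expression columns")
  labels <- clust$labels[cells]
  cl_ids <- sort(unique(labels))
  raw <- matrix(NA_real_, length(cl_ids), length(markers),
                dimnames = list(as.character(cl_ids), names(markers)))
  for (ci in seq_along(cl_ids)) {
    in_cl <- cells[labels == cl_ids[ci]]
    for (ty in names(markers)) {
      raw[ci, ty] <- mean(expr[markers[[ty]], in_cl, drop = FALSE])
    }
  }
  z <- if (nrow(raw) > 1) scale(raw) else raw
  z[is.nan(z)] <- 0  # a type with identical means in every cluster carries no signal
  ann <- character(nrow(raw))
  names(ann) <- rownames(raw)
  for (ci in seq_len(nrow(raw))) {
    if (all(raw[ci, ] == 0)) {
      ann[ci] <- "ambiguous"
      next
    }
    zi <- z[ci, ]
    top <- max(zi)
    if (sum(zi >= top - 1e-12) > 1) ann[ci] <- "ambiguous" else ann[ci] <- names(markers)[which.max(zi)]
  }
  clust$annotation_of <- ann
  clust$marker_scores <- z
  clust$cell_annotation <- stats::setNames(ann[as.character(labels)], cells)
  clust
}

#' Full single-cell clustering pipeline
#'
#' QC filter -> median size factors -> log10 normalization -> variable-gene
#' selection -> PCA -> KNN graph -> Louvain -> marker annotation, with all
#' parameters taken from an [default_config()] object.
#'
#' @param counts raw UMI count matrix (genes x cells).
#' @param config an `analysis_config`; `cell_cycle_genes` falls back to the
#'   shipped list when empty.
#' @param markers marker table for [annotate_clusters()].
#' @return list with `qc`, `size_factors`, `expr`, `variable`, `embedding`,
#'   `graph`, `clustering`.
#' @export
sc_cluster_pipeline <- function(counts, config = default_config(),
                                markers = default_markers()) {
  cc <- config$cell_cycle_genes
  if (!length(cc)) cc <- default_cell_cycle_genes()
  qc <- qc_filter(counts, config$min_cell_umi)
  sf <- compute_size_factors(qc$counts)
  expr <- normalize_log10(qc$counts, sf)
  vg <- select_variable_genes(expr, config$n_variable_genes,
                              config$exclusion_patterns, cc)
  emb <- run_pca(expr[vg$selected, , drop = FALSE], config$n_pcs)
  graph <- build_knn_graph(emb, config$knn_k)
  clust <- louvain_cluster(graph, config$louvain_resolution, config$rng_seed)
  clust <- annotate_clusters(clust, expr, markers)
  list(qc = qc$report, size_factors = sf, expr = expr, variable = vg,
       embedding = emb, graph = graph, clustering = clust)
}
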