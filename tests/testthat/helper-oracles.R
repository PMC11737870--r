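# Independent oracles and small fixture builders used across the suite.

# Literal step-up definition of BH adjusted p-values:
# for the i-th smallest p, q = min_{j >= i} m * p_(j) / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by direct summation of the pmf.
hyper_tail_brute <- function(k, set_size, universe_size, query_size) {
  ks <- k:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Tiny count matrix with explicit totals per cell (one dominant gene carries
# the remainder so column sums are exact).
toy_counts <- function(totals, n_genes = 4, gene_prefix = "g") {
  n <- length(totals)
  m <- matrix(1L, nrow = n_genes, ncol = n,
              dimnames = list(paste0(gene_prefix, seq_len(n_genes)),
                              paste0("cell", seq_len(n))))
  m[1, ] <- as.integer(totals - (n_genes - 1))
  stopifnot(all(colSums(m) == totals))
  m
}

# Minimal bulk metadata for a condition x timepoint x replicate grid.
toy_bulk_metadata <- function(timepoints, replicates,
                              conditions = c("control", "trained")) {
  md <- expand.grid(replicate = seq_len(replicates), timepoint_days = timepoints,
                    condition = conditions, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  md$column_id <- sprintf("%s_d%02d_r%d", md$condition, md$timepoint_days, md$replicate)
  md[, c("column_id", "condition", "timepoint_days", "replicate")]
}
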