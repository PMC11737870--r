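#!/usr/bin/env Rscript

# Single-cell preprocessing and clustering of the simulated CD11b+ sort:
# QC (cells < 200 UMIs out, undetected genes out), median size factors,
# log10(x+1), top-425 variable genes by the mean-CV noise model, 40-PC
# embedding, Louvain on the k=20 KNN graph, marker-based annotation.
# Run analysis/01_simulate_data.R first.

suppressPackageStartupMessages(library(trainomics))

counts <- read_count_matrix("results/sim_sc/counts.tsv", "tsv")
truth <- utils::read.delim("results/sim_sc/truth.tsv", stringsAsFactors = FALSE)

res <- sc_cluster_pipeline(counts, default_config())
print(res$qc)
print(res$clustering)

cl <- res$clustering
labels <- data.frame(column_id = names(cl$labels),
                     cluster = unname(cl$labels),
                     annotation = unname(cl$cell_annotation[names(cl$labels)]))
labels$truth_type <- truth$cell_type[match(labels$column_id, truth$column_id)]
agreement <- mean(labels$annotation == labels$truth_type)
message("annotated-label agreement with simulated truth: ", round(agreement, 4))

dir.create("results/sc_cluster", showWarnings = FALSE, recursive = TRUE)
utils::write.table(labels, "results/sc_cluster/labels.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(column_id = rownames(res$embedding$coordinates),
                              res$embedding$coordinates[, 1:10], check.names = FALSE),
                   "results/sc_cluster/embedding_pc1-10.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(cluster = rownames(cl$marker_scores),
                              annotation = unname(cl$annotation_of),
                              round(cl$marker_scores, 3), check.names = FALSE),
                   "results/sc_cluster/marker_scores.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(res$variable$selected, "results/sc_cluster/variable_genes.txt")
message("wrote results/sc_cluster/")
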