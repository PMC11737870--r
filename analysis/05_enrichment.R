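#!/usr/bin/env Rscript

# Over-representation analysis of the kinetics-called training genes.
# The universe is every gene in the prepared bulk matrix; the collection is
# a synthetic "curated pathway" built from the simulation truth (80% of the
# planted program plus decoys) alongside size-matched random sets, so the
# expected outcome is known. Run 01 and 03 first.

suppressPackageStartupMessages(library(trainomics))

query <- readLines("results/kinetics/training_genes.txt")
tab <- utils::read.delim("results/kinetics/integral_difference.tsv",
                         stringsAsFactors = FALSE)
universe <- tab$gene_id
truth <- utils::read.delim("results/sim_bulk/truth.tsv", stringsAsFactors = FALSE)

set.seed(5L)
program_set <- unique(c(sample(truth$gene_id, round(0.8 * nrow(truth))),
                        sample(setdiff(universe, truth$gene_id), 20)))
sets <- c(list(TRAINING_PROGRAM = program_set),
          stats::setNames(lapply(1:5, function(i) sample(universe, length(program_set))),
                          paste0("RANDOM_", 1:5)))

res <- ora(query, universe, sets, fdr_q = 0.05)
print(res[, c("set", "overlap", "set_size", "p_value", "q_value", "pass")])

dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
utils::write.table(res, "results/enrichment/ora.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/enrichment/ora.tsv")
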