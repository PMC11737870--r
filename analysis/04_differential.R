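#!/usr/bin/env Rscript

# Differential expression on the bulk time course: a pooled two-sided
# t-test of all control vs all trained samples (10% FDR, minimal twofold),
# one-way ANOVA across the trained timepoints (5% FDR, minimal twofold),
# and the union of per-timepoint control-vs-trained t-test contrasts.
# Run analysis/01_simulate_data.R and 03_kinetics.R first.

suppressPackageStartupMessages(library(trainomics))

counts <- read_count_matrix("results/sim_bulk/counts.tsv", "tsv", layer_tag = "reads")
md <- read_sample_metadata("results/sim_bulk/metadata.tsv")
tc <- prepare_bulk(counts, md, floor = 3)
expr <- tc$values
md <- tc$samples

pooled <- ttest_deg(expr,
                    md$column_id[md$condition == "control"],
                    md$column_id[md$condition == "trained"],
                    fdr_q = 0.10, min_fold = 2)
message("pooled control vs trained t-test: ", sum(pooled$pass), " DEGs")

trained_md <- md[md$condition == "trained", ]
kin_anova <- anova_deg(expr[, trained_md$column_id],
                       as.character(trained_md$timepoint_days),
                       fdr_q = 0.05, min_fold = 2)
message("ANOVA across trained timepoints: ", sum(kin_anova$pass), " DEGs")

contrasts <- lapply(c(14, 30), function(d) {
  list(a = md$column_id[md$condition == "control" & md$timepoint_days == d],
       b = md$column_id[md$condition == "trained" & md$timepoint_days == d])
})
names(contrasts) <- paste0("day", c(14, 30))
mc <- multi_contrast_union(expr, contrasts, fdr_q = 0.05, min_fold = 2)
message("union over per-timepoint contrasts: ", nrow(mc$union), " DEGs")

dir.create("results/differential", showWarnings = FALSE, recursive = TRUE)
utils::write.table(pooled, "results/differential/pooled_ttest.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(kin_anova, "results/differential/trained_timepoint_anova.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(mc$union, "results/differential/contrast_union.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/differential/")
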