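#!/usr/bin/env Rscript

# Generate the two synthetic datasets the downstream analyses run on:
#  - a two-condition (control / trained) splenic CD11b+ scRNA-seq experiment,
#    768 cells per condition, 6 cell types, with a STAT1-style training
#    program planted in trained classical monocytes;
#  - a bulk vaccination time course (days 3/14/30/45/60, 3 replicates per
#    condition x timepoint, 5000 genes, 5% training-responsive).
# Ground truth is written beside each dataset.

suppressPackageStartupMessages(library(trainomics))

seed <- 1L

message("simulating single-cell experiment ...")
sc <- simulate_sc_counts(sc_sim_spec(rng_seed = seed))
write_simulation(sc, "results/sim_sc")
message("  ", nrow(sc$counts), " genes x ", ncol(sc$counts), " cells; ",
        "median total UMI ", median(colSums(sc$counts)))

message("simulating bulk time course ...")
bulk <- simulate_bulk_timecourse(bulk_sim_spec(rng_seed = seed + 1L))
write_simulation(bulk, "results/sim_bulk")
message("  ", nrow(bulk$counts), " genes x ", ncol(bulk$counts), " samples; ",
        nrow(bulk$truth), " training-responsive genes planted")
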