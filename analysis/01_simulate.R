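#!/usr/bin/env Rscript
# Stage 1: generate the ground-truth dataset for the seven-condition
# rIIS / TF-knockdown design (16,000 genes, 2 replicates per group,
# DAF-16-dominant combination rule) and persist it as TSV.
library(riisregulome)

seed <- 1
out <- "results/sim"

truth <- generate_truth(16000, generator_config(), seed = seed)
sim <- simulate_counts(truth, default_design(), seed = seed)
write_dataset(sim, out)

cat("Simulated", nrow(truth), "genes x", ncol(sim$counts$counts),
    "samples (seed", seed, ")\n")
cat("TF target genes: DAF-16", sum(truth$effect_daf16 != 0),
    "| SKN-1", sum(truth$effect_skn1 != 0),
    "| HSF-1", sum(truth$effect_hsf1 != 0), "\n")
cat("Dataset written to", out, "\n")
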