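#!/usr/bin/env Rscript
# Stage 2: normalized expression (RPKM/CPM) and sample-level QC.
# Replicates of the same condition should be each other's nearest
# neighbours in z-scored log-CPM space, mirroring replicate-concordance
# dendrograms of RNA-seq studies.
library(riisregulome)

ds <- load_simulated_dataset("results/sim")
x <- ds$counts

r <- rpkm(x)
utils::write.table(
  data.frame(gene_id = rownames(r), round(r, 4), check.names = FALSE),
  "results/rpkm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

qc <- qc_summary(x)
cat("PC1/PC2 explained variance:",
    sprintf("%.1f%% / %.1f%%", 100 * qc$var_explained[1],
            100 * qc$var_explained[2]), "\n")
same_group <- function(id) {
  g <- x$samples$group[x$samples$sample_id == id]
  x$samples$group[x$samples$sample_id == qc$nearest[[id]]] == g
}
ok <- vapply(x$samples$sample_id, same_group, logical(1))
cat(sum(ok), "of", length(ok),
    "samples have a same-group nearest neighbour\n")
utils::write.table(
  data.frame(sample_id = rownames(qc$scores), round(qc$scores[, 1:3], 4)),
  "results/qc_pca_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
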