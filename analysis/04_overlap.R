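#!/usr/bin/env Rscript
# Stage 4: gene-set overlap statistics. Detection overlaps per comparison
# (representation factor + log-space hypergeometric p, which stays exact
# for p-values thousands of orders of magnitude below double underflow)
# and the three-way Venn partition of TF-regulated genes.
library(riisregulome)

ds <- load_simulated_dataset("results/sim")
x <- ds$counts
N <- nrow(x$counts)

rows <- list()
for (nm in names(default_comparisons())) {
  cmp <- default_comparisons()[[nm]]
  ov <- overlap_test(detected_genes(x, cmp$test_group),
                     detected_genes(x, cmp$baseline_group),
                     universe_size = N)
  rows[[nm]] <- data.frame(comparison = cmp$name, k = ov$k, m = ov$m,
                           n = ov$n, N = ov$N, rf = round(ov$rf, 3),
                           log10_p = round(ov$log10_p, 2),
                           p = format_log10_p(ov$log10_p))
  cat(sprintf("%-28s common %5d  RF=%.2f  P=%s\n", cmp$name, ov$k, ov$rf,
              format_log10_p(ov$log10_p)))
}
utils::write.table(do.call(rbind, rows), "results/detection_overlaps.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

tf_sets <- lapply(c(daf16 = "daf16", skn1 = "skn1", hsf1 = "hsf1"),
                  function(tf) {
  de <- utils::read.delim(file.path("results", paste0("de_", tf, ".tsv")),
                          stringsAsFactors = FALSE)
  de$gene_id[de$call != "unchanged"]
})
vs <- venn_summary(venn_partition(tf_sets))
cat("\nTF-regulated gene sharing (percent of union):\n")
print(vs)
utils::write.table(vs, "results/venn_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
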