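#!/usr/bin/env Rscript
# Stage 3: oriented differential expression for the five study
# comparisons, restricted to genes detected in both conditions of each
# comparison (condition-exclusive genes are discarded). Calls use the
# |FC| >= 1.5, p <= 0.05 convention; "activated" = up in the test group.
library(riisregulome)

ds <- load_simulated_dataset("results/sim")
x <- ds$counts

for (nm in names(default_comparisons())) {
  cmp <- default_comparisons()[[nm]]
  cg <- common_genes(detected_genes(x, cmp$test_group),
                     detected_genes(x, cmp$baseline_group))
  de <- de_test(x, cmp, genes = cg$common)
  utils::write.table(as.data.frame(de),
                     file.path("results", paste0("de_", nm, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-28s common %5d | activated %4d | repressed %4d\n",
              cmp$name, length(cg$common),
              sum(de$call == "activated"), sum(de$call == "repressed")))
}
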