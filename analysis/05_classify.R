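#!/usr/bin/env Rscript
# Stage 5: the comparative classification layer — rIIS-dependence
# cross-tabs per TF, reversal-to-control analysis, TF-vs-rIIS quadrant
# classification and the combinatorial dominance tabulation. Under the
# DAF-16-dominant generative rule, DAF-16's concordance with the rIIS
# direction should be the strict maximum.
library(riisregulome)

res <- run_pipeline(run_config(seed = 1, out_dir = "results/pipeline"))

cat("rIIS-dependence cross-tabs (combined fraction of rIIS-DE genes):\n")
for (tf in names(res$crosstabs)) {
  ct <- res$crosstabs[[tf]]
  cat(sprintf("  %-6s %4d/%4d = %.1f%%\n", tf, ct$combined_num,
              ct$combined_den, ct$combined_fraction_pct))
}

cat("\nReversal-to-control fractions (activated / repressed):\n")
for (tf in names(res$reversal)) {
  s <- res$reversal[[tf]]$summary
  cat(sprintf("  %-6s %.2f / %.2f\n", tf, s$fraction[1], s$fraction[2]))
}

cat("\nTF-vs-rIIS quadrant same-direction fractions:\n")
for (tf in names(res$quadrants)) {
  cat(sprintf("  %-6s %.1f%%\n", tf, res$quadrants[[tf]]$same_direction_pct))
}

cat("\nDominance concordance:\n")
print(round(res$dominance$concordance, 3))
cat("verdict:", res$summary$dominance$verdict, "\n")
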