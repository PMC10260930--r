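#!/usr/bin/env Rscript

# Stage 4: compare deficiency-associated residues to the remainder.
#
# For each of the 14 features, 63-element subsamples of the majority
# group are drawn 10,000 times; the one-sided p-value is the share of
# subsample medians exceeding the deficiency group's median. Low p
# indicates the deficiency group sits high on that feature; high p (near
# 1) indicates it sits low.

suppressPackageStartupMessages(library(fvrin))

fm <- read.csv("results/data/calibrated_features.csv", stringsAsFactors = FALSE)
res <- compare_feature_groups(fm, n_iter = 10000L, seed = 20260104L)
write.csv(res, "results/group_stats.csv", row.names = FALSE)

cat(sprintf("%d deficiency vs %d other residues, 10,000 iterations/feature\n",
            res$n_small[1], res$n_large[1]))
for (i in seq_len(nrow(res))) {
  dir <- if (res$p_value[i] < 0.5) "higher" else "lower"
  cat(sprintf("  %-18s median %6.3f vs %6.3f  p = %-6.4g (deficient %s)\n",
              res$feature[i], res$median_small[i], res$median_large_full[i],
              res$p_value[i], dir))
}
sig <- res$feature[res$p_value < 0.01 | res$p_value > 0.99]
cat("features with a clear one-sided signal:", paste(sig, collapse = ", "), "\n")
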