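#!/usr/bin/env Rscript

# Stage 3: criticality groups and the supercritical set.
#
# The degree / log10-betweenness plane is split into 4 uniform bins per
# axis; the extreme bin combinations give the HDHB / LDHB / LDLB groups.
# The Pareto front over (degree, betweenness, closeness) gives the
# supercritical residues.

suppressPackageStartupMessages(library(fvrin))

cent <- read.csv("results/centralities.csv", stringsAsFactors = FALSE)

crit <- bin_criticality(cent, n_bins = 4L)
super <- pareto_supercritical(cent)
tab <- crit$labels
tab$supercritical <- tab$residue %in% super
write.csv(tab, "results/criticality.csv", row.names = FALSE)

cat("bin grid (degree):", paste(round(crit$grid$degree_edges, 3), collapse = " "), "\n")
cat("bin grid (log10 betweenness):",
    paste(round(crit$grid$logbet_edges, 3), collapse = " "), "\n")
print(table(tab$label))
cat(sprintf("supercritical residues (%d): %s\n", length(super),
            paste(super, collapse = ", ")))
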