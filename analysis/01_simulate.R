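#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Three files emulate what the real analysis consumes: a protein structure
# (here a generated poly-alanine fold written as PDB), a per-residue
# conservation table, and a deficiency label table. A larger calibrated
# feature table (1317 residues, 63 labelled deficient, planted effects)
# is also written for the statistics and classification stages.

suppressPackageStartupMessages(library(fvrin))

seed <- 20260101L
out_data <- "results/data"
dir.create(out_data, showWarnings = FALSE, recursive = TRUE)

paths <- write_synthetic_fixtures(out_data, n_res = 150L, n_deficient = 12L,
                                  torsions = c(-57, -47), seed = seed)
cat("wrote structure fixture:", paths[["structure"]], "\n")
cat("wrote conservation table:", paths[["conservation"]], "\n")
cat("wrote label table:", paths[["labels"]], "\n")

fm <- generate_feature_table(paper_calibrated_spec(seed = seed))
write.csv(fm, file.path(out_data, "calibrated_features.csv"), row.names = FALSE)
cat(sprintf(
  "calibrated feature table: %d residues, %d labelled deficient (%.2f%%)\n",
  nrow(fm), sum(fm$label), 100 * mean(fm$label)))
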