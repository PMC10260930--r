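#!/usr/bin/env Rscript

# Stage 5: tune the five-classifier ensemble and score every residue.
#
# Grid search under 10-fold stratified cross-validation, over the four
# preprocessing combinations (PCA yes/no x ADASYN oversampling yes/no,
# always standardized), selected by mean validation AUC. The tuned
# models then vote: the per-residue score 0-5 counts classifiers that
# predict a substitution there to be detrimental.

suppressPackageStartupMessages(library(fvrin))

seed <- 20260105L
fm <- read.csv("results/data/calibrated_features.csv", stringsAsFactors = FALSE)

lb <- cv_leaderboard(fm, preset = "fast", k = 10L, seed = seed)
write.csv(lb, "results/cv_leaderboard.csv", row.names = FALSE)
cat("leaderboard (mean validation AUC):\n")
print(lb[order(-lb$auc_mean), c("estimator", "combo", "auc_mean", "auc_sd")],
      row.names = FALSE, digits = 3)
cat(sprintf("best configuration: %s / %s, AUC %.3f\n",
            lb$estimator[which.max(lb$auc_mean)],
            lb$combo[which.max(lb$auc_mean)], max(lb$auc_mean)))

models <- train_final_models(fm, select_best(lb), seed = seed)
votes <- ensemble_vote(models, fm)
votes <- votes[order(-votes$vote), ]
write.csv(votes, "results/votes.csv", row.names = FALSE)

shares <- 100 * table(factor(votes$vote, levels = 0:5)) / nrow(votes)
cat("vote score distribution (% of residues):\n")
print(round(shares, 1))
cat(sprintf("safe to substitute (vote 0): %.1f%%; flagged by all five: %.1f%%\n",
            shares[["0"]], shares[["5"]]))
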