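#!/usr/bin/env Rscript
# Recombination vs homoplasy at the simulated loci. The study set is
# simulated without recombination, so four-gamete incompatibilities inside
# cores reflect repeat mutation only and the randomization null should not
# reject; a contrast set with one forced crossover shows what a true
# recombination signal looks like.

library(pointcen)

res <- run_pipeline("results/run_config.yaml")
rec <- res$recombination
core <- rec[rec$region == "core", ]
cat("Per-core four-gamete summary (no recombination simulated):\n")
print(core[, c("locus", "S", "n_incompatible_pairs", "rmin", "k_obs", "p_value")],
      row.names = FALSE)
cat(sprintf("cores with p < 0.05: %d/16\n", sum(core$p_value < 0.05)))
joint <- rec[rec$region == "joint_after_removal", ]
cat(sprintf("loci with incompatibilities after removing inferred homoplasies: %d/16\n",
            sum(joint$n_incompatible_pairs > 0)))

# contrast: a forced crossover between diverged blocks
hits <- vapply(1:50, function(i) {
  s <- simulate_coalescent_alignment(n_crossovers = 1, seed = 900 + i)
  h <- homoplasy_analysis(s$alignment, n_reps = 500, seed = i)
  c(pairs = nrow(h$incompatible_pairs) > 0, rmin = h$rmin)
}, numeric(2))
cat(sprintf("with one crossover: incompatibilities in %.0f%% of 50 replicates, mean R_min %.1f\n",
            100 * mean(hits["pairs", ]), mean(hits["rmin", ])))

write.table(rec, "results/recombination_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
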