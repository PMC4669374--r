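#!/usr/bin/env Rscript
# Colony development (CD) and ecophysiological diversity (EP) indices of the
# synthetic cohort, per plate and summarized per hydrocarbon. The generator
# is calibrated so the cohort mean CD sits in the 26.4-27.3 band reported
# for the real communities (a K-strategist-dominated profile).

suppressPackageStartupMessages(library(pahsoiltox))

colony <- read_colony_counts("results/synthetic/colony_counts.csv")
idx <- colony_indices(colony)
summ <- index_summary(idx)

dir.create("results", showWarnings = FALSE)
write.csv(idx, "results/colony_indices.csv", row.names = FALSE)
write.csv(summ, "results/index_summary.csv", row.names = FALSE)

cat("Per-hydrocarbon CD and EP (synthetic cohort):\n")
print(summ, digits = 4)
cat(sprintf("\nCohort mean CD = %.2f (closed-form design value 26.85)\n",
            mean(idx$cd)))
cat(sprintf("Cohort mean EP = %.3f (uniform emergence would give 1)\n",
            mean(idx$ep)))
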