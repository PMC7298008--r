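#!/usr/bin/env Rscript
# Stage 2: normalize and assign molecular subtypes.
#
# Reads the simulated cohort back from disk (exercising the IO layer),
# log2/median-normalizes it, and runs the two-stage Ward/Euclidean
# marker-panel clustering with the double-negative z-score rule.

library(bltsub)

expr <- read_expression("results/cohort/expression.tsv")
panels <- read_panels("results/cohort/panels.gmt")
truth <- read_labels("results/cohort/truth_labels.csv")

norm <- normalize_expression(expr)
labels <- cluster_subtypes(norm, panels$LUMINAL28, panels$BASAL20,
                           dn_threshold = -0.5)
write_labels(labels, "results/labels_clustered.csv")

agreement <- mean(labels == truth[names(labels)])
cat("Cluster-assigned subtypes:\n")
print(table(labels))
cat(sprintf("Agreement with simulation truth: %.1f%%\n", 100 * agreement))
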