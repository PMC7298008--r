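#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the default synthetic cohort (200 tumours: 100 luminal, 85 basal,
# 15 double-negative; marker shift 2 log2 units, noise sd 1, seed 17) and
# writes its expression TSV, truth labels, IHC table, marker-panel GMT and
# resolved config under results/cohort/.

library(bltsub)

cohort <- generate_cohort(synthetic_config(seed = 17))
write_cohort(cohort, "results/cohort")

cat("Simulated cohort:", ncol(cohort$expression), "samples x",
    nrow(cohort$expression), "genes\n")
print(table(cohort$truth_labels))
cat("written to results/cohort/\n")
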