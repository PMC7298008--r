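#!/usr/bin/env Rscript
# Stage 6: the immunohistochemistry surrogate classifier.
#
# Applies the rule-based GATA3/KRT5-6 caller to the simulated staining
# proportions, summarizes the calls against the mRNA subtypes, and assesses
# the quantitative two-marker logistic model by leave-one-out CV on the
# luminal/basal cases.

library(bltsub)

ihc <- read.csv("results/cohort/ihc.csv", stringsAsFactors = FALSE)
labels <- read_labels("results/labels_clustered.csv")

calls <- classify_ihc(ihc, pos_threshold = 0.10, strong_threshold = 0.50)
write.csv(calls, "results/ihc_calls.csv", row.names = FALSE)

cont <- contingency_summary(calls, labels)
write.csv(cont$table, "results/ihc_contingency.csv", row.names = FALSE)
cat("IHC call x mRNA subtype contingency (counts and %):\n")
print(cont$table[cont$table$count > 0, ])
cat(sprintf("overall rule concordance: %.1f%%\n", 100 * cont$concordance))

lb <- ihc$case[labels[ihc$case] != "double_negative"]
loocv <- suppressWarnings(
  lr_loocv(ihc[ihc$case %in% lb, ], labels, marker_pair = c("gata3", "krt5_6")))
write.csv(loocv$predictions, "results/ihc_loocv.csv", row.names = FALSE)
cat(sprintf("GATA3 + KRT5/6 logistic LOOCV accuracy (luminal vs basal): %.1f%%\n",
            100 * loocv$accuracy))
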