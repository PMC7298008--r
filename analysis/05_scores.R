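#!/usr/bin/env Rscript
# Stage 5: EMT and immune phenotype scores.
#
# Fits the E-cadherin-anchored correlation weights on the cohort, computes
# the cohort-centred EMT score, and the median-centred immune and checkpoint
# scores; summarizes the per-subtype means.

library(bltsub)

expr <- read_expression("results/cohort/expression.tsv")
panels <- read_panels("results/cohort/panels.gmt")
labels <- read_labels("results/labels_clustered.csv")

norm <- normalize_expression(expr)
sig <- emt_weights(norm, panels$EMT76$genes, anchor = "CDH1")
emt <- emt_score(norm, sig)
immune <- median_signature_score(norm, panels$IMMUNE128)
checkpoint <- median_signature_score(norm, panels$CHECKPOINT12)

write.csv(data.frame(sample = names(emt), emt = unname(emt),
                     immune = immune[names(emt)],
                     checkpoint = checkpoint[names(emt)]),
          "results/phenotype_scores.csv", row.names = FALSE)

gm <- function(x) round(vapply(split(x[names(labels)], labels), mean, 0), 2)
cat("per-subtype mean EMT score (negative = activated EMT):\n"); print(gm(emt))
cat("per-subtype mean immune score:\n"); print(gm(immune))
cat("per-subtype mean checkpoint score:\n"); print(gm(checkpoint))
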