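#!/usr/bin/env Rscript
# Stage 3: how confident are the subtype assignments?
#
# Computes pairwise cluster prediction strength (50 random halvings, k-means
# with k = 2) and per-sample Bayes posterior strengths on the z-scored
# marker-gene space, with the >= 80% strong-assignment rule.

library(bltsub)
library(jsonlite)

expr <- read_expression("results/cohort/expression.tsv")
panels <- read_panels("results/cohort/panels.gmt")
labels <- read_labels("results/labels_clustered.csv")

norm <- normalize_expression(expr)
markers <- union(panels$LUMINAL28$genes, panels$BASAL20$genes)
zmark <- row_zscore(norm[markers, ])

pairs <- list(c("luminal", "basal"), c("luminal", "double_negative"),
              c("basal", "double_negative"))
ps <- lapply(pairs, function(p)
  prediction_strength(zmark, labels, p, k = 2, n_splits = 50,
                      seed = 1701, zscore = FALSE))
names(ps) <- vapply(pairs, paste, "", collapse = "_vs_")

post <- posterior_strengths(fit_posterior_model(zmark, labels), zmark)
write.csv(post, "results/posterior_strengths.csv", row.names = FALSE)
strong <- vapply(split(post$strong, labels[post$sample]), mean, 0)

write_json(list(prediction_strength = lapply(ps, `[[`, "ps_mean"),
                strong_posterior_fraction = as.list(strong)),
           "results/validity.json", auto_unbox = TRUE, digits = NA,
           pretty = TRUE)

for (nm in names(ps))
  cat(sprintf("prediction strength %-30s %.3f\n", nm, ps[[nm]]$ps_mean))
cat("fraction of strong (>=80%) posterior assignments per subtype:\n")
print(round(strong, 3))
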