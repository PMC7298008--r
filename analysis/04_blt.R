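#!/usr/bin/env Rscript
# Stage 4: the BLT score.
#
# LASSO-selects 28 of the 48 candidate markers, fits the linear discriminant,
# scores every sample (positive = luminal-like), grid-searches the cutoff,
# evaluates the ROC optimal point and 5-fold stratified CV accuracy, and
# writes the model, the per-sample scores with the LD1/LD2 projection, and
# the ROC curve.

library(bltsub)
library(jsonlite)

expr <- read_expression("results/cohort/expression.tsv")
panels <- read_panels("results/cohort/panels.gmt")
labels <- read_labels("results/labels_clustered.csv")

norm <- normalize_expression(expr)
markers <- union(panels$LUMINAL28$genes, panels$BASAL20$genes)

selected <- select_markers_lasso(norm, labels, markers, target_nonzero = 28)
split_panel <- table(ifelse(selected %in% panels$LUMINAL28$genes,
                            "luminal", "basal"))
cat(sprintf("LASSO selected %d genes (%s luminal + %s basal)\n",
            length(selected), split_panel[["luminal"]], split_panel[["basal"]]))

model <- fit_blt(norm, labels, selected)
scores <- blt_score(model, norm)
proj <- ld_projection(model, norm)

lb <- labels %in% c("luminal", "basal")
roc <- roc_curve(scores[lb], labels[lb])
cv <- cv_accuracy(norm, labels, selected, folds = 5, seed = 1702)

write_json(list(genes = model$selected_genes,
                weights = as.list(model$weights),
                ld2_weights = as.list(model$ld2_weights),
                cutoff = model$cutoff,
                auc = roc$auc, roc_optimal = as.list(roc$optimal),
                cv_accuracy = cv$accuracy),
           "results/blt_model.json", auto_unbox = TRUE, digits = NA,
           pretty = TRUE)
write.csv(data.frame(sample = names(scores), blt = unname(scores),
                     LD1 = proj$LD1, LD2 = proj$LD2,
                     predicted = ifelse(scores > model$cutoff,
                                        "luminal", "basal")),
          "results/blt_scores.csv", row.names = FALSE)
write.csv(data.frame(threshold = roc$thresholds,
                     sensitivity = roc$sensitivity,
                     specificity = roc$specificity),
          "results/roc_curve.csv", row.names = FALSE)

cat(sprintf("cutoff %.3f; AUC %.4f; optimal sens %.3f / spec %.3f\n",
            model$cutoff, roc$auc, roc$optimal["sensitivity"],
            roc$optimal["specificity"]))
cat(sprintf("luminal above cutoff: %.1f%%; basal below: %.1f%%\n",
            100 * mean(scores[labels == "luminal"] > model$cutoff),
            100 * mean(scores[labels == "basal"] <= model$cutoff)))
cat(sprintf("5-fold stratified CV accuracy: %.1f%%\n", 100 * cv$accuracy))
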