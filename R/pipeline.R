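#' Run the full subtyping pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> normalize -> cluster -> validity -> BLT ->
#' phenotype scores -> IHC, writing per-stage outputs and a JSON manifest of
#' every metric to `out_dir`. Each random stage consumes a seed derived from
#' the global seed and the stage name, so stages are reproducible standalone;
#' the derived seeds are recorded in the manifest.
#'
#' @param config a `synthetic_config` (or list of overrides passed to it).
#' @param out_dir output directory; created if needed. `NULL` skips writing.
#' @param dn_threshold double-negative z-score threshold (default -0.5).
#' @param target_nonzero LASSO target gene count (default 28).
#' @param n_splits prediction-strength splits (default 50).
#' @param folds CV folds (default 5).
#' @return the manifest list, invisibly if `out_dir` is given.
#' @export
run_all <- function(config = synthetic_config(), out_dir = NULL,
                    dn_threshold = -0.5, target_nonzero = 28,
                    n_splits = 50, folds = 5) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  seed <- config$seed
  seeds <- vapply(c("ps", "cv"), function(s) derive_seed(seed, s), 0L)
  warnings_log <- character()
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    cohort <- generate_cohort(config)
    norm <- normalize_expression(cohort$expression)
    panels <- cohort$panels

    labels <- cluster_subtypes(norm, panels$luminal, panels$basal,
                               dn_threshold = dn_threshold)
    agreement <- mean(labels == cohort$truth_labels)

    marker_genes <- union(panels$luminal$genes, panels$basal$genes)
    zmark <- row_zscore(norm[marker_genes, , drop = FALSE])
    present <- table(factor(labels, SUBTYPES))
    pairs <- utils::combn(SUBTYPES[present >= 4], 2, simplify = FALSE)
    ps <- lapply(pairs, function(p)
      prediction_strength(zmark, labels, p, k = 2, n_splits = n_splits,
                          seed = seeds[["ps"]], zscore = FALSE))
    names(ps) <- vapply(pairs, paste, "", collapse = "_vs_")

    post_model <- fit_posterior_model(zmark, labels)
    post <- posterior_strengths(post_model, zmark)
    strong_frac <- vapply(split(post$strong, labels[post$sample]), mean, 0)

    selected <- select_markers_lasso(norm, labels, marker_genes,
                                     target_nonzero = target_nonzero)
    model <- fit_blt(norm, labels, selected)
    scores <- blt_score(model, norm)
    lb <- labels %in% c("luminal", "basal")
    roc <- roc_curve(scores[lb], labels[lb])
    sens_at_cut <- mean(scores[labels == "luminal"] > model$cutoff)
    spec_at_cut <- mean(scores[labels == "basal"] <= model$cutoff)
    cv <- cv_accuracy(norm, labels, selected, folds = folds,
                      seed = seeds[["cv"]])
    proj <- ld_projection(model, norm)

    sig <- emt_weights(norm, panels$emt$genes, anchor = "CDH1")
    emt <- emt_score(norm, sig)
    immune <- median_signature_score(norm, panels$immune)
    checkpoint <- median_signature_score(norm, panels$checkpoint)
    group_mean <- function(x) vapply(split(x[names(labels)], labels), mean, 0)

    ihc_calls <- classify_ihc(cohort$ihc_records)
    lb_ids <- names(labels)[lb]
    loocv <- lr_loocv(cohort$ihc_records[cohort$ihc_records$case %in% lb_ids, ],
                      labels, marker_pair = c("gata3", "krt5_6"))
    cont <- contingency_summary(ihc_calls, labels)

    manifest <- list(
      seed = seed, derived_seeds = as.list(seeds),
      n_samples = ncol(norm),
      subtype_counts = as.list(table(labels)),
      clustering_agreement = agreement,
      prediction_strength = lapply(ps, `[[`, "ps_mean"),
      strong_posterior_fraction = as.list(strong_frac),
      n_selected_genes = length(selected),
      blt_cutoff = model$cutoff,
      blt_auc = roc$auc,
      roc_optimal = as.list(roc$optimal),
      sensitivity_at_cutoff = sens_at_cut,
      specificity_at_cutoff = spec_at_cut,
      cv_accuracy = cv$accuracy,
      emt_group_means = as.list(group_mean(emt)),
      immune_group_means = as.list(group_mean(immune)),
      checkpoint_group_means = as.list(group_mean(checkpoint)),
      ihc_loocv_accuracy = loocv$accuracy,
      ihc_concordance = cont$concordance,
      warnings = warnings_log
    )

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_cohort(cohort, file.path(out_dir, "cohort"))
      write_labels(labels, file.path(out_dir, "labels_clustered.csv"))
      utils::write.csv(post, file.path(out_dir, "posterior_strengths.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(genes = model$selected_genes, weights = as.list(model$weights),
             ld2_weights = as.list(model$ld2_weights),
             cutoff = model$cutoff, seed = seed),
        file.path(out_dir, "blt_model.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(
        data.frame(sample = names(scores), blt = unname(scores),
                   LD1 = proj$LD1, LD2 = proj$LD2,
                   predicted = ifelse(scores > model$cutoff, "luminal", "basal")),
        file.path(out_dir, "blt_scores.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
                   specificity = roc$specificity),
        file.path(out_dir, "roc_curve.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(sample = names(emt), emt = unname(emt),
                   immune = immune[names(emt)],
                   checkpoint = checkpoint[names(emt)]),
        file.path(out_dir, "phenotype_scores.csv"), row.names = FALSE)
      utils::write.csv(ihc_calls, file.path(out_dir, "ihc_calls.csv"),
                       row.names = FALSE)
      utils::write.csv(cont$table, file.path(out_dir, "ihc_contingency.csv"),
                       row.names = FALSE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(manifest)
  }, warning = log_warn)
}
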