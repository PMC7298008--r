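#' LASSO selection of discriminative marker genes
#'
#' Fits an L1-regularized multinomial model (grouped penalty, so a gene is in
#' or out across all classes) over the glmnet lambda path and picks the path
#' point whose count of genes with any non-zero coefficient is closest to
#' `target_nonzero`; ties go to the larger lambda (sparser model). Selection
#' is invariant to the listing order of the candidate panel.
#'
#' @param m normalized expression matrix.
#' @param labels named subtype labels.
#' @param candidate_genes the candidate panel (e.g. 28 luminal + 20 basal).
#' @param target_nonzero desired number of selected genes (default 28).
#' @return character vector of selected genes, in matrix row order.
#' @export
select_markers_lasso <- function(m, labels, candidate_genes, target_nonzero = 28) {
  labels <- assert_samples_match(m, labels)
  genes <- intersect(rownames(m), candidate_genes)
  if (length(genes) < 2) stop("fewer than 2 candidate genes present in matrix")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 5)) warning("class with fewer than 5 samples")
  X <- t(m[genes, , drop = FALSE])
  fit <- glmnet::glmnet(X, y, family = "multinomial",
                        type.multinomial = "grouped", standardize = TRUE)
  nz_count <- vapply(seq_along(fit$lambda), function(i) {
    cf <- lapply(glmnet::coef.glmnet(fit, s = fit$lambda[i]),
                 function(b) as.matrix(b)[-1, 1])
    sum(Reduce(`+`, lapply(cf, abs)) > 0)
  }, 0L)
  ok <- which(nz_count >= 2)
  if (length(ok) == 0) stop("no lambda on the path selects at least 2 genes")
  dist <- abs(nz_count[ok] - target_nonzero)
  best <- ok[dist == min(dist)]
  best <- best[which.max(fit$lambda[best])]
  cf <- lapply(glmnet::coef.glmnet(fit, s = fit$lambda[best]),
               function(b) as.matrix(b)[-1, 1])
  sel <- genes[Reduce(`+`, lapply(cf, abs)) > 0]
  rownames(m)[rownames(m) %in% sel]
}

#' Fit the basal-to-luminal transition (BLT) discriminant model
#'
#' Solves the standard between/within generalized eigenproblem on the
#' selected genes, with the within-group covariance pooled and shrunk toward
#' its diagonal exactly as in [fit_posterior_model()]. The BLT weights are the
#' negated first-discriminant coefficients, globally sign-fixed so that the
#' mean training BLT score of the luminal group exceeds that of the basal
#' group. With three training groups a second discriminant (LD2) is retained
#' for the two-dimensional projection. The score cutoff is grid-searched on
#' the training scores with double-negatives excluded.
#'
#' @param m normalized expression matrix.
#' @param labels named subtype labels (2 or 3 groups, >= 2 samples each).
#' @param selected_genes genes entering the discriminant (e.g. LASSO output).
#' @param shrinkage optional fixed covariance shrinkage in [0, 1].
#' @return list of class `blt_model`: `selected_genes`, `weights`,
#'   `ld2_weights` (or NULL), `cutoff`, `groups`, `training_metadata`.
#' @export
fit_blt <- function(m, labels, selected_genes, shrinkage = NULL) {
  labels <- assert_samples_match(m, labels)
  genes <- intersect(rownames(m), selected_genes)
  if (length(genes) < 2) stop("need at least 2 selected genes present")
  groups <- intersect(SUBTYPES, unique(labels))
  if (!all(c("luminal", "basal") %in% groups))
    stop("training labels must contain both luminal and basal")
  cnt <- table(factor(labels, groups))
  if (any(cnt < 2)) stop("fewer than 2 samples in group: ",
                         paste(names(cnt)[cnt < 2], collapse = ", "))

  X <- t(m[genes, , drop = FALSE])
  grand <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X))
  B <- matrix(0, ncol(X), ncol(X))
  for (g in groups) {
    rows <- labels == g
    mu_g <- colMeans(X[rows, , drop = FALSE])
    C <- sweep(X[rows, , drop = FALSE], 2, mu_g)
    W <- W + crossprod(C)
    B <- B + sum(rows) * tcrossprod(mu_g - grand)
  }
  W <- W / (nrow(X) - length(groups))
  lambda <- if (is.null(shrinkage)) {
    centered <- X
    for (g in groups) {
      rows <- labels == g
      centered[rows, ] <- sweep(X[rows, , drop = FALSE], 2,
                                colMeans(X[rows, , drop = FALSE]))
    }
    min(max(shrinkage_intensity(centered), 0), 1)
  } else shrinkage
  W <- (1 - lambda) * W + lambda * diag(diag(W), nrow(W))

  eW <- eigen(W, symmetric = TRUE)
  if (min(eW$values) <= 0) stop("within-group covariance not positive-definite after shrinkage")
  Whalf_inv <- eW$vectors %*% diag(1 / sqrt(eW$values), length(eW$values)) %*% t(eW$vectors)
  eS <- eigen(Whalf_inv %*% B %*% Whalf_inv, symmetric = TRUE)
  ndisc <- min(length(groups) - 1, ncol(X))
  A <- Whalf_inv %*% eS$vectors[, seq_len(ndisc), drop = FALSE]

  weights <- -A[, 1]
  scores <- as.vector(X %*% weights)
  if (mean(scores[labels == "luminal"]) <= mean(scores[labels == "basal"]))
    weights <- -weights
  names(weights) <- genes

  ld2 <- NULL
  if (ndisc >= 2) {
    ld2 <- A[, 2]
    if (ld2[which.max(abs(ld2))] < 0) ld2 <- -ld2  # deterministic sign
    names(ld2) <- genes
  }

  model <- structure(list(selected_genes = genes, weights = weights,
                          ld2_weights = ld2, cutoff = NA_real_,
                          groups = groups, shrinkage = lambda,
                          training_metadata = list(
                            n = as.list(cnt), discriminants = ndisc)),
                     class = "blt_model")
  lb <- labels %in% c("luminal", "basal")
  model$cutoff <- optimal_cutoff(blt_score(model, m)[lb], labels[lb])
  model
}

#' @export
print.blt_model <- function(x, ...) {
  cat(sprintf("<blt_model> %d genes, cutoff %.3f, shrinkage %.3f, %d discriminant(s)\n",
              length(x$selected_genes), x$cutoff, x$shrinkage,
              x$training_metadata$discriminants))
  invisible(x)
}

#' Unidimensional BLT score
#'
#' `score[s] = sum_i W_i * E[i, s]`: the weighted sum of the model genes'
#' normalized expression, positive in luminal and negative in basal tumours
#' by the training orientation.
#'
#' @param model a `blt_model`.
#' @param m normalized expression matrix containing every model gene.
#' @return named numeric vector of per-sample scores.
#' @export
blt_score <- function(model, m) {
  missing <- setdiff(model$selected_genes, rownames(m))
  if (length(missing) > 0)
    stop("model genes absent from matrix: ", paste(missing, collapse = ", "))
  as.vector(model$weights %*% m[model$selected_genes, , drop = FALSE]) |>
    stats::setNames(colnames(m))
}

#' Grid-searched score cutoff minimizing misclassification
#'
#' Evaluates 1000 evenly spaced candidate cutoffs over the score range;
#' samples scoring above a candidate are called luminal, the rest basal. The
#' candidate with the fewest misclassifications wins; among ties, the
#' candidate closest to the median of the tied set.
#'
#' @param scores numeric BLT scores.
#' @param labels matching labels, luminal and basal only.
#' @param grid_size number of candidates (default 1000).
#' @return the cutoff value.
#' @export
optimal_cutoff <- function(scores, labels, grid_size = 1000) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  if (!all(c("luminal", "basal") %in% labels))
    stop("both luminal and basal scores are required")
  grid <- seq(min(scores), max(scores), length.out = grid_size)
  lum <- scores[labels == "luminal"]
  bas <- scores[labels == "basal"]
  miss <- vapply(grid, function(c) sum(lum <= c) + sum(bas > c), 0)
  tied <- grid[miss == min(miss)]
  tied[which.min(abs(tied - stats::median(tied)))]
}

#' ROC curve of BLT scores for luminal vs basal separation
#'
#' Luminal is the positive class; a sample is called positive when its score
#' is at least the threshold. Thresholds run over all unique scores plus
#' +/- infinity, AUC is the trapezoid over the curve, and the optimal
#' operating point minimizes `(1 - sensitivity)^2 + (1 - specificity)^2`
#' (the point closest to the top-left corner).
#'
#' @param scores numeric scores.
#' @param labels matching labels; double-negatives must be removed upstream.
#' @return list of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `optimal` (threshold, sensitivity, specificity).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "luminal"
  if (!any(pos) || all(pos)) stop("both classes required for ROC")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), 0)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (utils::head(sens[ord], -1) + utils::tail(sens[ord], -1)) / 2)
  d2 <- (1 - sens)^2 + (1 - spec)^2
  i <- which.min(d2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 optimal = c(threshold = thr[i], sensitivity = sens[i],
                             specificity = spec[i])),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f; optimal sens %.3f / spec %.3f at %.3f\n",
              x$auc, x$optimal["sensitivity"], x$optimal["specificity"],
              x$optimal["threshold"]))
  invisible(x)
}

#' Stratified k-fold cross-validated subtype accuracy
#'
#' Folds preserve subtype proportions to within one sample per class. In each
#' fold the discriminant machinery is refit on the training samples over the
#' FIXED selected gene set (marker selection is not re-run) and held-out
#' samples are assigned to the posterior-maximizing subtype under the
#' Gaussian shared-covariance model. The accuracy is averaged over folds.
#'
#' @param m normalized expression matrix.
#' @param labels named subtype labels.
#' @param selected_genes fixed gene set from [select_markers_lasso()].
#' @param folds number of folds (default 5; reduced with a warning if a class
#'   is smaller than `folds`).
#' @param seed RNG seed for fold assignment.
#' @return list: `accuracy` (mean over folds), `fold_accuracy`, `folds`.
#' @export
cv_accuracy <- function(m, labels, selected_genes, folds = 5, seed = 1) {
  labels <- assert_samples_match(m, labels)
  cls <- unique(labels)
  min_n <- min(table(labels))
  if (min_n < folds) {
    warning("smallest class has ", min_n, " samples; folds reduced to ", min_n)
    folds <- min_n
  }
  if (folds < 2) stop("cannot cross-validate with fewer than 2 folds")
  set.seed(seed)
  fold_id <- stats::setNames(integer(length(labels)), names(labels))
  for (g in cls) {
    idx <- sample(names(labels)[labels == g])
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- vapply(seq_len(folds), function(f) {
    te <- names(fold_id)[fold_id == f]
    tr <- setdiff(names(labels), te)
    if (length(unique(labels[tr])) < 2) stop("training fold with a single class")
    mod <- fit_posterior_model(m[selected_genes, tr, drop = FALSE], labels[tr])
    pred <- posterior_strengths(mod, m[selected_genes, te, drop = FALSE])
    mean(pred$assigned == labels[te])
  }, 0)
  list(accuracy = mean(acc), fold_accuracy = acc, folds = folds,
       fold_assignment = fold_id)
}

#' Two-dimensional discriminant projection (LD1, LD2)
#'
#' LD1 is the negated BLT score by construction; LD2 is the second
#' discriminant, available only for models trained on three groups.
#'
#' @param model a `blt_model` with two discriminants.
#' @param m normalized expression matrix.
#' @return data.frame: sample, LD1, LD2.
#' @export
ld_projection <- function(model, m) {
  if (is.null(model$ld2_weights))
    stop("model was trained on 2 groups; no second discriminant available")
  data.frame(sample = colnames(m),
             LD1 = -blt_score(model, m),
             LD2 = as.vector(model$ld2_weights %*% m[model$selected_genes, , drop = FALSE]),
             row.names = NULL)
}
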