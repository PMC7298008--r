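#' E-cadherin-anchored EMT signature weights
#'
#' Each signature gene's weight is its Pearson correlation with the anchor
#' gene (CDH1 by default) across the cohort, so epithelial genes weigh
#' positively and mesenchymal genes negatively; the anchor's own weight is 1.
#' Genes absent from the matrix are dropped and zero-variance genes get
#' weight 0, each with a warning.
#'
#' @param m normalized expression matrix.
#' @param signature_genes the EMT signature gene list.
#' @param anchor anchor gene identifier (default "CDH1").
#' @param method correlation flavor, "pearson" (default) or "spearman".
#' @return list of class `emt_signature`: `genes`, `weights`, `anchor`.
#' @export
emt_weights <- function(m, signature_genes, anchor = "CDH1",
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!anchor %in% rownames(m)) stop("anchor gene absent: ", anchor)
  if (ncol(m) < 3) stop("need at least 3 samples to estimate correlations")
  a <- m[anchor, ]
  if (stats::sd(a) == 0) stop("anchor gene has zero variance")
  genes <- unique(c(anchor, signature_genes))
  absent <- setdiff(genes, rownames(m))
  if (length(absent) > 0) {
    warning("signature genes absent from matrix dropped: ",
            paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  w <- vapply(genes, function(g) {
    x <- m[g, ]
    if (stats::sd(x) == 0) {
      warning("zero-variance signature gene gets weight 0: ", g)
      return(0)
    }
    stats::cor(x, a, method = method)
  }, 0)
  structure(list(genes = genes, weights = w, anchor = anchor),
            class = "emt_signature")
}

#' Weighted-sum EMT score, cohort-centered
#'
#' `score_j = sum_i w_i G_ij` over the signature genes, then centered by
#' subtracting the cohort mean so the grand mean is zero. Negative scores
#' indicate an activated (mesenchymal) EMT state.
#'
#' @param m normalized expression matrix.
#' @param sig an `emt_signature` fitted on a compatible cohort.
#' @return named numeric vector of per-sample scores, mean zero.
#' @export
emt_score <- function(m, sig) {
  genes <- intersect(sig$genes, rownames(m))
  if (length(genes) == 0) stop("no signature genes present in matrix")
  raw <- as.vector(sig$weights[genes] %*% m[genes, , drop = FALSE])
  stats::setNames(raw - mean(raw), colnames(m))
}

#' Median-based signature score (immune / checkpoint panels)
#'
#' For each sample, the median expression over the panel genes minus the
#' grand mean of those medians across the cohort, so the scores sum to zero.
#' Requires at least half the panel genes to be present.
#'
#' @param m normalized expression matrix.
#' @param panel a `marker_panel` (e.g. the 128-gene immune panel).
#' @return named numeric vector of per-sample scores, mean zero.
#' @export
median_signature_score <- function(m, panel) {
  if (ncol(m) == 0) stop("empty cohort")
  genes <- intersect(panel$genes, rownames(m))
  if (length(genes) < length(panel$genes) / 2)
    stop(sprintf("panel '%s': only %d of %d genes present (need >= 50%%)",
                 panel$name, length(genes), length(panel$genes)))
  med <- apply(m[genes, , drop = FALSE], 2, stats::median)
  med - mean(med)
}
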