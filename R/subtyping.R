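#' Two-stage luminal / basal / double-negative subtype assignment
#'
#' Stage 1 clusters samples by Ward's criterion on Euclidean distances over
#' the z-scored union of the luminal and basal marker panels, cut at k = 2;
#' each cluster is named after the panel with the higher mean z-scored
#' expression among its members. Stage 2 relabels as double-negative every
#' sample whose cohort-wide mean z-score falls below `dn_threshold` on BOTH
#' panels, then re-clusters the remaining samples at k = 2 (z-scores
#' recomputed within that subset) and names the clusters as in stage 1.
#' Double-negative separation is a single pass: stage-2 re-clustering cannot
#' create new double-negatives.
#'
#' @param m normalized expression matrix (genes x samples).
#' @param luminal_panel,basal_panel `marker_panel` objects; each must share at
#'   least 3 genes with the matrix.
#' @param dn_threshold z-score threshold below which, on both panels, a sample
#'   is called double-negative (default -0.5).
#' @return named character vector of labels with `provenance = "clustered"`.
#' @export
cluster_subtypes <- function(m, luminal_panel, basal_panel, dn_threshold = -0.5) {
  if (ncol(m) < 3) stop("need at least 3 samples to cluster")
  lg <- intersect(luminal_panel$genes, rownames(m))
  bg <- intersect(basal_panel$genes, rownames(m))
  if (length(lg) < 3 || length(bg) < 3)
    stop(sprintf("panel/gene overlap too small (luminal %d, basal %d; need >= 3 each)",
                 length(lg), length(bg)))

  z <- row_zscore(m[union(lg, bg), , drop = FALSE])
  labels <- cluster_and_name(z, lg, bg)

  lum_mean <- colMeans(z[lg, , drop = FALSE])
  bas_mean <- colMeans(z[bg, , drop = FALSE])
  dn <- lum_mean < dn_threshold & bas_mean < dn_threshold

  if (any(dn)) {
    labels[dn] <- "double_negative"
    rest <- colnames(m)[!dn]
    if (length(rest) >= 3) {
      z2 <- row_zscore(m[union(lg, bg), rest, drop = FALSE])
      labels[rest] <- cluster_and_name(z2, lg, bg)
    }
  }
  structure(labels, provenance = "clustered")
}

# Ward/Euclidean k=2 clustering of the columns of a z-scored marker matrix,
# clusters named by the dominant panel; degenerate naming is an error.
cluster_and_name <- function(z, lum_genes, bas_genes) {
  cl <- stats::cutree(stats::hclust(stats::dist(t(z)), method = "ward.D2"), k = 2)
  nm <- vapply(1:2, function(k) {
    cols <- cl == k
    lum <- mean(z[lum_genes, cols, drop = FALSE])
    bas <- mean(z[bas_genes, cols, drop = FALSE])
    if (lum > bas) "luminal" else "basal"
  }, "")
  if (nm[1] == nm[2])
    stop(sprintf(paste0("degenerate separation: both clusters look %s ",
                        "(cluster sizes %d/%d); marker contrast too weak"),
                 nm[1], sum(cl == 1), sum(cl == 2)))
  stats::setNames(nm[cl], colnames(z))
}
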