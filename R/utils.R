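#' @keywords internal
"_PACKAGE"

SUBTYPES <- c("luminal", "basal", "double_negative")

#' Row-wise z-scoring of an expression matrix
#'
#' Standardizes each gene (row) across samples to mean 0 / sd 1, the scale on
#' which Euclidean marker-panel clustering and prediction strength operate.
#' Zero-variance rows are returned as all zeros.
#'
#' @param m numeric matrix, genes in rows.
#' @return matrix of the same shape.
#' @export
row_zscore <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

# nearest integer, halves away from zero (contingency percentages)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# per-stage seed derived from a global seed; stays well below 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10000L + sum(utf8ToInt(stage)) %% 9973L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_samples_match <- function(m, labels) {
  if (is.null(names(labels))) {
    stopifnot(length(labels) == ncol(m))
    names(labels) <- colnames(m)
  }
  missing <- setdiff(colnames(m), names(labels))
  if (length(missing) > 0)
    stop("samples without labels: ", paste(utils::head(missing, 5), collapse = ", "))
  labels[colnames(m)]
}
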