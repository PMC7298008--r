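#' Read a gene-by-sample expression matrix from tab-separated text
#'
#' First column holds gene identifiers, header row sample identifiers.
#' Duplicate gene rows are collapsed by their mean (with a warning); duplicate
#' sample identifiers and non-numeric cells are errors. The returned matrix is
#' flagged as linear-scale.
#'
#' @param path path to a TSV file.
#' @return numeric matrix (genes x samples) with attribute `expr_scale = "linear"`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed expression file: ", path)
  genes <- df[[1]]
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1]]))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   df[[j + 1]][bad[1]], genes[bad[1]], samples[j]))
    if (anyNA(v)) stop("missing values are not supported (sample ", samples[j], ")")
    vals[, j] <- v
  }
  if (anyDuplicated(genes)) {
    warning("duplicate gene rows collapsed by mean: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
    sums <- rowsum(vals, genes)
    vals <- sums / as.vector(table(genes)[rownames(sums)])
    genes <- rownames(vals)
  }
  rownames(vals) <- genes
  attr(vals, "expr_scale") <- "linear"
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' @param m numeric matrix, genes in rows.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("gene", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform and median-normalize an expression matrix
#'
#' Each value becomes `log2(raw) - median(log2(raw))` over the genes of its
#' sample, so every sample's median is exactly zero afterwards. Refuses input
#' already on the normalized scale and non-positive values.
#'
#' @param m linear-scale expression matrix with strictly positive values.
#' @return matrix with attribute `expr_scale = "log_median_normalized"`.
#' @export
normalize_expression <- function(m) {
  sc <- attr(m, "expr_scale") %||% "linear"
  if (sc == "log_median_normalized")
    stop("input is already log/median-normalized; refusing to renormalize")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("normalization requires finite, strictly positive linear-scale values")
  lg <- log2(m)
  out <- sweep(lg, 2, apply(lg, 2, stats::median))
  attr(out, "expr_scale") <- "log_median_normalized"
  out
}

#' Construct a marker panel
#'
#' @param name panel name.
#' @param genes character vector of gene identifiers (deduplicated, order kept).
#' @param role one of luminal, basal, emt, immune, checkpoint, custom.
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(name, genes, role = "custom") {
  role <- match.arg(role, c("luminal", "basal", "emt", "immune", "checkpoint", "custom"))
  genes <- as.character(genes)
  if (length(genes) == 0) stop("empty panel: ", name)
  if (anyDuplicated(genes)) {
    warning("panel '", name, "': duplicate genes removed, order preserved")
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, genes = genes, role = role), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel> %s (%s): %d genes\n", x$name, x$role, length(x$genes)))
  invisible(x)
}

#' Read marker panels from a GMT or plain gene-list file
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; a file without
#' tabs is read as a single one-gene-per-line panel named after the file.
#'
#' @param path input file.
#' @param roles optional named character vector mapping panel name to role.
#' @return list of `marker_panel` objects.
#' @export
read_panels <- function(path, roles = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty panel file: ", path)
  if (any(grepl("\t", lines))) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(fields, `[[`, "", 1)
    if (anyDuplicated(nm)) stop("duplicate panel names: ",
                                paste(nm[duplicated(nm)], collapse = ", "))
    panels <- lapply(fields, function(f) {
      if (length(f) < 3) stop("GMT line with no genes: ", f[1])
      marker_panel(f[1], f[-(1:2)], role = unname(roles[f[1]] %||% "custom"))
    })
  } else {
    nm <- sub("\\.[^.]*$", "", basename(path))
    panels <- list(marker_panel(nm, lines, role = unname(roles[nm] %||% "custom")))
  }
  names(panels) <- vapply(panels, `[[`, "", "name")
  panels
}

#' Write marker panels to a GMT file
#'
#' @param panels list of `marker_panel` objects.
#' @param path output path.
#' @export
write_panels <- function(panels, path) {
  lines <- vapply(panels, function(p)
    paste(c(p$name, p$role, p$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read subtype labels from CSV (`sample,label`)
#'
#' @param path CSV path.
#' @return named character vector with a `provenance` attribute.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$label), SUBTYPES)
  if (length(bad) > 0) stop("unknown subtype labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("sample labeled more than once")
  structure(stats::setNames(df$label, df$sample), provenance = "file")
}

#' Write subtype labels to CSV
#'
#' @param labels named character vector of subtype labels.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(sample = names(labels), label = unname(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
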