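#' Default marker panels for synthetic cohorts
#'
#' Builds the panel collection the generator shifts: 28 luminal and 20 basal
#' markers (headed by the canonical urothelial symbols), a 76-gene EMT
#' signature split into epithelial-adhesion genes (anchored on CDH1, with
#' CLDN1 and TJP1) and EMT transcription factors (including ZEB2), a 128-gene
#' immune panel and a 12-gene checkpoint panel. Synthetic identifiers
#' (LUM003..., BAS006..., EMTE.../EMTF..., IMM..., CPT...) fill the panels out
#' so panel files and real symbol lists are interchangeable.
#'
#' @return named list of `marker_panel` objects
#'   (luminal, basal, emt, immune, checkpoint).
#' @export
default_panels <- function() {
  luminal <- c("KRT20", "GATA3", "FOXA1", "XBP1", "CD24", "UPK2",
               sprintf("LUM%03d", 7:28))
  basal <- c("KRT5", "KRT6A", "KRT14", "CDH3", "CD44",
             sprintf("BAS%03d", 6:20))
  emt_epi <- c("CDH1", "CLDN1", "TJP1", sprintf("EMTE%03d", 4:38))
  emt_tf <- c("ZEB2", sprintf("EMTF%03d", 2:38))
  list(
    luminal    = marker_panel("LUMINAL28", luminal, "luminal"),
    basal      = marker_panel("BASAL20", basal, "basal"),
    emt        = marker_panel("EMT76", c(emt_epi, emt_tf), "emt"),
    immune     = marker_panel("IMMUNE128", sprintf("IMM%03d", 1:128), "immune"),
    checkpoint = marker_panel("CHECKPOINT12", sprintf("CPT%03d", 1:12), "checkpoint")
  )
}

# epithelial half of the EMT panel (downshifted in double-negatives); the
# remainder of the panel are the EMT transcription factors (upshifted)
emt_epithelial_genes <- function(emt_panel) {
  emt_panel$genes[seq_len(38)]
}

#' Configuration for a synthetic bladder-cancer cohort
#'
#' Defaults emulate a TCGA-like cohort of 200 tumours: a luminal majority, a
#' basal group of which a fifth co-expresses luminal markers, and a small
#' double-negative minority with an activated-EMT, immune-hot profile.
#' All shifts are in log2 units on a Normal(6, 1) per-gene baseline.
#'
#' @param n_luminal,n_basal,n_double_negative samples per subtype.
#' @param effect_size_markers log2 shift of a subtype's own marker panel.
#' @param effect_size_emt log2 EMT shift in double-negatives
#'   (epithelial genes down, transcription factors up).
#' @param effect_size_immune log2 immune/checkpoint shift in double-negatives;
#'   basal samples get half of it.
#' @param noise_sd per-gene log2 standard deviation.
#' @param n_background_genes unshifted filler genes.
#' @param frac_basal_coexpressing fraction of basal samples that also gain
#'   half the marker shift on the luminal panel.
#' @param seed integer RNG seed.
#' @param ihc_beta_params per-subtype list of per-marker `c(shape1, shape2)`
#'   Beta parameters for staining proportions.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_luminal = 100, n_basal = 85,
                             n_double_negative = 15,
                             effect_size_markers = 2,
                             effect_size_emt = 2,
                             effect_size_immune = 2,
                             noise_sd = 1,
                             n_background_genes = 500,
                             frac_basal_coexpressing = 0.2,
                             seed = 17,
                             ihc_beta_params = default_ihc_beta_params()) {
  cfg <- list(n_luminal = n_luminal, n_basal = n_basal,
              n_double_negative = n_double_negative,
              effect_size_markers = effect_size_markers,
              effect_size_emt = effect_size_emt,
              effect_size_immune = effect_size_immune,
              noise_sd = noise_sd,
              n_background_genes = n_background_genes,
              frac_basal_coexpressing = frac_basal_coexpressing,
              seed = as.integer(seed),
              ihc_beta_params = ihc_beta_params)
  if (any(c(n_luminal, n_basal, n_double_negative, n_background_genes) < 0))
    stop("counts must be non-negative")
  if (n_luminal + n_basal + n_double_negative < 2)
    stop("need at least 2 samples in total")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (frac_basal_coexpressing < 0 || frac_basal_coexpressing > 1)
    stop("frac_basal_coexpressing must be in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

#' Default per-subtype Beta parameters for IHC staining proportions
#'
#' Reciprocal GATA3 / KRT5-6 staining: luminal tumours GATA3-high and
#' KRT5/6-low, basal the reverse, double-negative low on both; KRT20/UPK2
#' (luminal) and KRT14 (basal) follow the same pattern with more overlap.
#'
#' @return nested list: subtype -> marker -> `c(shape1, shape2)`.
#' @export
default_ihc_beta_params <- function() {
  list(
    luminal = list(gata3 = c(8, 2), krt20 = c(5, 5), upk2 = c(4, 6),
                   krt5_6 = c(1, 19), krt14 = c(1, 19)),
    basal = list(gata3 = c(1, 19), krt20 = c(2, 8), upk2 = c(1, 9),
                 krt5_6 = c(8, 2), krt14 = c(6, 4)),
    double_negative = list(gata3 = c(1, 19), krt20 = c(1, 19), upk2 = c(1, 19),
                           krt5_6 = c(1, 19), krt14 = c(1, 19))
  )
}

#' Generate a synthetic expression + IHC cohort
#'
#' Draws linear-scale expression as `2^Normal(mu_g + shift, sd)` where the
#' per-gene baseline `mu_g ~ Normal(6, 1)` is drawn once per seed. Subtype
#' shifts: luminal samples `+delta` on the luminal panel; basal samples
#' `+delta` on the basal panel, a configured fraction of them additionally
#' `+delta/2` on the luminal panel; double-negative samples are unshifted on
#' both marker panels but carry the EMT shift (epithelial genes
#' `-delta_EMT`, EMT transcription factors `+delta_EMT`) and the full immune
#' shift; basal samples get half the immune shift. The checkpoint panel
#' follows the immune grading. IHC staining proportions are drawn per subtype
#' from the configured Beta distributions.
#'
#' @param config a `synthetic_config`.
#' @return list of class `synthetic_cohort` with elements `expression`
#'   (linear scale), `truth_labels`, `ihc_records` (data.frame), `panels`,
#'   `baseline_log2_mean`, `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  panels <- default_panels()
  genes <- c(unlist(lapply(panels, `[[`, "genes"), use.names = FALSE),
             if (config$n_background_genes > 0)
               sprintf("BG%04d", seq_len(config$n_background_genes)))
  stopifnot(!anyDuplicated(genes))

  n <- c(luminal = config$n_luminal, basal = config$n_basal,
         double_negative = config$n_double_negative)
  labels <- rep(names(n), n)
  samples <- sprintf("S%03d_%s", seq_along(labels),
                     c(luminal = "L", basal = "B", double_negative = "D")[labels])

  set.seed(config$seed)
  mu <- stats::setNames(stats::rnorm(length(genes), 6, 1), genes)

  shift <- matrix(0, length(genes), length(samples),
                  dimnames = list(genes, samples))
  d <- config$effect_size_markers
  lum_genes <- panels$luminal$genes
  bas_genes <- panels$basal$genes
  shift[lum_genes, labels == "luminal"] <- d
  shift[bas_genes, labels == "basal"] <- d
  basal_idx <- which(labels == "basal")
  n_co <- round(config$frac_basal_coexpressing * length(basal_idx))
  if (n_co > 0) {
    co <- sample(basal_idx, n_co)
    shift[lum_genes, co] <- shift[lum_genes, co] + d / 2
  }
  epi <- emt_epithelial_genes(panels$emt)
  tf <- setdiff(panels$emt$genes, epi)
  dn <- labels == "double_negative"
  shift[epi, dn] <- shift[epi, dn] - config$effect_size_emt
  shift[tf, dn] <- shift[tf, dn] + config$effect_size_emt
  imm <- c(panels$immune$genes, panels$checkpoint$genes)
  shift[imm, labels == "basal"] <- shift[imm, labels == "basal"] +
    config$effect_size_immune / 2
  shift[imm, dn] <- shift[imm, dn] + config$effect_size_immune

  logx <- mu + shift + matrix(stats::rnorm(length(shift), 0, config$noise_sd),
                              nrow(shift), ncol(shift))
  expr <- 2^logx
  dimnames(expr) <- dimnames(shift)
  attr(expr, "expr_scale") <- "linear"

  ihc <- data.frame(case = samples, stringsAsFactors = FALSE)
  markers <- names(config$ihc_beta_params$luminal)
  for (mk in markers) {
    ihc[[mk]] <- vapply(labels, function(l) {
      p <- config$ihc_beta_params[[l]][[mk]]
      stats::rbeta(1, p[1], p[2])
    }, 0)
  }

  structure(list(
    expression = expr,
    truth_labels = structure(stats::setNames(labels, samples), provenance = "truth"),
    ihc_records = ihc,
    panels = panels,
    baseline_log2_mean = mu,
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d samples (%s), seed %d\n",
              nrow(x$expression), ncol(x$expression),
              paste(table(factor(x$truth_labels, SUBTYPES)), collapse = "/"),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to an output directory
#'
#' Writes the expression TSV, truth-label CSV, IHC CSV, panel GMT and the
#' resolved configuration as plain-text key-value pairs.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_labels(cohort$truth_labels, file.path(dir, "truth_labels.csv"))
  utils::write.csv(cohort$ihc_records, file.path(dir, "ihc.csv"),
                   row.names = FALSE, quote = FALSE)
  write_panels(cohort$panels, file.path(dir, "panels.gmt"))
  cfg <- cohort$config
  scalar <- !vapply(cfg, is.list, TRUE)
  writeLines(paste0(names(cfg)[scalar], "=",
                    vapply(cfg[scalar], function(v) format(v, digits = 15), "")),
             file.path(dir, "config.txt"))
  invisible(dir)
}
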