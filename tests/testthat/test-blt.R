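signal_noise_cohort <- function(n_per = 40, delta = 3, seed = 21) {
  set.seed(seed)
  signal <- sprintf("SIG%02d", 1:10)
  noise <- sprintf("NOI%02d", 1:38)
  genes <- c(signal, noise)
  samples <- sprintf("S%03d", seq_len(2 * n_per))
  labels <- stats::setNames(rep(c("luminal", "basal"), each = n_per), samples)
  m <- matrix(rnorm(length(genes) * length(samples)), length(genes),
              dimnames = list(genes, samples))
  m[signal, labels == "luminal"] <- m[signal, labels == "luminal"] + delta
  list(m = m, labels = labels, signal = signal, genes = genes)
}

test_that("LASSO keeps signal genes and is invariant to panel ordering", {
  d <- signal_noise_cohort()
  sel <- select_markers_lasso(d$m, d$labels, d$genes, target_nonzero = 10)
  expect_true(all(sel %in% d$signal))
  expect_gte(length(sel), 5)
  sel_rev <- select_markers_lasso(d$m, d$labels, rev(d$genes),
                                  target_nonzero = 10)
  expect_identical(sel, sel_rev)
})

test_that("discriminant direction matches the closed-form Fisher solution", {
  set.seed(30)
  n <- 60
  genes <- c("g1", "g2")
  samples <- sprintf("S%03d", 1:(2 * n))
  labels <- stats::setNames(rep(c("luminal", "basal"), each = n), samples)
  L <- matrix(c(1, 0.6, 0, 0.8), 2) # shared covariance chol factor
  X <- matrix(rnorm(4 * n), ncol = 2) %*% t(L)
  X[labels == "luminal", ] <- sweep(X[labels == "luminal", ], 2, c(2, 1), "+")
  m <- t(X)
  dimnames(m) <- list(genes, samples)

  model <- fit_blt(m, labels, genes, shrinkage = 0)
  # closed form from the same data: W^-1 (mu_L - mu_B), pooled empirical W
  muL <- rowMeans(m[, labels == "luminal"])
  muB <- rowMeans(m[, labels == "basal"])
  Cw <- (cov(X[labels == "luminal", ]) * (n - 1) +
         cov(X[labels == "basal", ]) * (n - 1)) / (2 * n - 2)
  fisher <- solve(Cw, muL - muB)
  cosang <- sum(model$weights * fisher) /
    sqrt(sum(model$weights^2) * sum(fisher^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-8)
  # orientation: luminal mean score above basal mean score
  s <- blt_score(model, m)
  expect_gt(mean(s[labels == "luminal"]), mean(s[labels == "basal"]))
})

test_that("discriminant direction cross-checks against MASS::lda", {
  skip_if_not_installed("MASS")
  d <- signal_noise_cohort(n_per = 50, delta = 2, seed = 33)
  genes <- d$genes[1:12]
  model <- fit_blt(d$m[genes, ], d$labels, genes, shrinkage = 0)
  ld <- MASS::lda(t(d$m[genes, ]), grouping = factor(d$labels[colnames(d$m)]))
  ref <- ld$scaling[, 1]
  cosang <- sum(model$weights * ref[names(model$weights)]) /
    sqrt(sum(model$weights^2) * sum(ref^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-6)
})

test_that("perfect collinearity is absorbed by covariance shrinkage", {
  d <- signal_noise_cohort(n_per = 20)
  m <- d$m[d$signal, ]
  m <- rbind(m, DUP01 = m[1, ]) # exact duplicate gene
  model <- fit_blt(m, d$labels, rownames(m))
  expect_true(all(is.finite(model$weights)))
  expect_gt(model$shrinkage, 0)
})

test_that("the BLT score is linear in expression", {
  d <- signal_noise_cohort(n_per = 15)
  model <- fit_blt(d$m, d$labels, d$signal)
  zero <- d$m * 0
  expect_equal(unname(blt_score(model, zero)), rep(0, ncol(d$m)))
  g <- d$signal[3]
  bumped <- d$m
  bumped[g, 1] <- bumped[g, 1] + 2.5
  expect_equal(blt_score(model, bumped)[1] - blt_score(model, d$m)[1],
               unname(model$weights[g] * 2.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # affine equivariance: scaling expression scales scores
  expect_equal(unname(blt_score(model, d$m * 3)),
               unname(3 * blt_score(model, d$m)), tolerance = 1e-12)
  expect_error(blt_score(model, d$m[-1, ]), "absent")
})

test_that("grid-searched cutoff matches the exhaustive midpoint oracle", {
  scores <- c(2, 3, 0.5, -1, -2, 1)
  labels <- c("luminal", "luminal", "luminal", "basal", "basal", "basal")
  cut <- optimal_cutoff(scores, labels)
  expect_equal(misclass_at(cut, scores, labels),
                   min_misclass_oracle(scores, labels))
  expect_equal(min_misclass_oracle(scores, labels), 1)

  # separated case: zero misclassification, cutoff inside the gap
  s2 <- c(1.5, 2, 4, -1.2, -3, -2)
  cut2 <- optimal_cutoff(s2, labels)
  expect_equal(misclass_at(cut2, s2, labels), 0)
  expect_true(cut2 > -1.2 && cut2 < 1.5)

  # antisymmetry under score negation + label swap, within grid resolution
  swapped <- ifelse(labels == "luminal", "basal", "luminal")
  res <- diff(range(scores)) / 999
  expect_lt(abs(optimal_cutoff(-scores, swapped) + cut), 2 * res)

  set.seed(41)
  for (i in 1:20) {
    s <- rnorm(12)
    l <- sample(rep(c("luminal", "basal"), 6))
    expect_equal(misclass_at(optimal_cutoff(s, l), s, l),
                     min_misclass_oracle(s, l))
  }
})

test_that("ROC handles separation, equals the U-statistic, and is null-calibrated", {
  sep <- roc_curve(c(3, 4, 5, -1, -2, 0), rep(c("luminal", "basal"), each = 3))
  expect_equal(sep$auc, 1, tolerance = 1e-12)
  expect_identical(unname(sep$optimal[c("sensitivity", "specificity")]), c(1, 1))

  set.seed(52)
  for (i in 1:20) {
    s <- sample(round(rnorm(30), 1)) # rounding forces ties
    l <- sample(rep(c("luminal", "basal"), 15))
    expect_equal(roc_curve(s, l)$auc, auc_u_oracle(s, l), tolerance = 1e-12)
  }

  set.seed(53)
  s <- rnorm(2000)
  l <- sample(rep(c("luminal", "basal"), 1000))
  expect_true(roc_curve(s, l)$auc > 0.47 && roc_curve(s, l)$auc < 0.53)
})

test_that("ROC cross-checks against pROC", {
  skip_if_not_installed("pROC")
  set.seed(54)
  s <- rnorm(60)
  l <- sample(rep(c("luminal", "basal"), 30))
  ours <- roc_curve(s, l)
  ref <- pROC::roc(response = l, predictor = s, levels = c("basal", "luminal"),
                   direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("stratified CV is exact on separable data and calibrated under the null", {
  d <- signal_noise_cohort(n_per = 30, delta = 6, seed = 61)
  cv <- cv_accuracy(d$m, d$labels, d$signal, folds = 5, seed = 1)
  expect_equal(cv$accuracy, 1)

  set.seed(62)
  n <- 300
  m <- matrix(rnorm(10 * n), 10,
              dimnames = list(paste0("g", 1:10), sprintf("S%03d", 1:n)))
  labels <- stats::setNames(rep(c("luminal", "basal", "double_negative"),
                                each = n / 3), colnames(m))
  cv0 <- cv_accuracy(m, labels, rownames(m), folds = 5, seed = 2)
  expect_true(cv0$accuracy >= 0.25 && cv0$accuracy <= 0.42)
})

test_that("CV folds preserve class proportions to within one sample", {
  d <- signal_noise_cohort(n_per = 23, seed = 63)
  cv <- cv_accuracy(d$m, d$labels, d$signal, folds = 5, seed = 7)
  for (g in unique(d$labels)) {
    per_fold <- table(factor(cv$fold_assignment[d$labels == g], 1:5))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  # small classes shrink the fold count with a warning
  lab <- d$labels
  lab[1:3] <- "double_negative"
  expect_warning(cv2 <- cv_accuracy(d$m, lab, d$signal, folds = 5, seed = 7),
                 "folds reduced")
  expect_equal(cv2$folds, 3)
})

test_that("LD projection is definitional and separates three synthetic groups", {
  ch <- generate_cohort(synthetic_config(seed = 17, effect_size_markers = 3))
  norm <- normalize_expression(ch$expression)
  genes <- union(ch$panels$luminal$genes, ch$panels$basal$genes)
  model <- fit_blt(norm, ch$truth_labels, genes)
  proj <- ld_projection(model, norm)
  expect_equal(proj$LD1, unname(-blt_score(model, norm)), tolerance = 1e-12)

  # projection of a group-mean expression vector sits at the projected centroid
  lum_cols <- ch$truth_labels == "luminal"
  mean_vec <- rowMeans(norm[, lum_cols, drop = FALSE])
  mm <- matrix(mean_vec, ncol = 1, dimnames = list(names(mean_vec), "mean"))
  pm <- ld_projection(model, mm)
  expect_equal(pm$LD1, mean(proj$LD1[lum_cols]), tolerance = 1e-9)
  expect_equal(pm$LD2, mean(proj$LD2[lum_cols]), tolerance = 1e-9)

  # groups barely overlap in (LD1, LD2) at this effect size
  overlap <- mapply(function(a, b) {
    ra <- range(proj$LD1[ch$truth_labels == a])
    rb <- range(proj$LD1[ch$truth_labels == b])
    max(0, min(ra[2], rb[2]) - max(ra[1], rb[1])) > 0
  }, c("luminal"), c("basal"))
  lum_scores <- proj$LD1[ch$truth_labels == "luminal"]
  bas_scores <- proj$LD1[ch$truth_labels == "basal"]
  expect_lt(mean(lum_scores), mean(bas_scores)) # LD1 = -BLT

  two_group <- fit_blt(norm[, !ch$truth_labels %in% "double_negative"],
                       ch$truth_labels[!ch$truth_labels %in% "double_negative"],
                       genes)
  expect_error(ld_projection(two_group, norm), "no second discriminant")
})
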