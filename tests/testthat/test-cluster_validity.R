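two_blob_matrix <- function(n_per = 30, gap = 10, sd = 0.5, p = 4, seed = 4) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p, 0, sd), n_per),
             matrix(rnorm(n_per * p, gap, sd), n_per))
  samples <- sprintf("S%03d", seq_len(2 * n_per))
  m <- t(X)
  dimnames(m) <- list(paste0("F", seq_len(p)), samples)
  labels <- stats::setNames(rep(c("luminal", "basal"), each = n_per), samples)
  list(m = m, labels = labels)
}

test_that("prediction strength is 1 for k = 1 and high for separated blobs", {
  d <- two_blob_matrix()
  ps1 <- prediction_strength(d$m, d$labels, c("luminal", "basal"),
                             k = 1, n_splits = 10, seed = 1, zscore = FALSE)
  expect_identical(ps1$ps_per_split, rep(1, 10))
  ps2 <- prediction_strength(d$m, d$labels, c("luminal", "basal"),
                             k = 2, n_splits = 50, seed = 1, zscore = FALSE)
  expect_true(all(ps2$ps_per_split >= 0 & ps2$ps_per_split <= 1))
  expect_gte(ps2$ps_mean, 0.95)
})

test_that("an artificially split single cloud has low prediction strength", {
  set.seed(7)
  n <- 200
  m <- t(matrix(rnorm(n * 4), n))
  dimnames(m) <- list(paste0("F", 1:4), sprintf("S%03d", 1:n))
  labels <- stats::setNames(rep(c("luminal", "basal"), each = n / 2),
                            colnames(m))
  ps <- prediction_strength(m, labels, c("luminal", "basal"),
                            k = 2, n_splits = 50, seed = 2, zscore = FALSE)
  expect_lt(ps$ps_mean, 0.80)
})

test_that("prediction strength agrees with a naive pair-counting oracle", {
  d <- two_blob_matrix(n_per = 20, gap = 4, sd = 1.5, seed = 6)
  ps <- prediction_strength(d$m, d$labels, c("luminal", "basal"),
                            k = 2, n_splits = 40, seed = 3, zscore = FALSE)
  oracle <- ps_naive_oracle(t(d$m), k = 2, n_splits = 40, seed = 13)
  expect_lt(abs(ps$ps_mean - oracle), 0.1)
})

test_that("prediction strength respects its seed and rejects undersized pairs", {
  d <- two_blob_matrix(n_per = 10)
  a <- prediction_strength(d$m, d$labels, c("luminal", "basal"),
                           n_splits = 5, seed = 9, zscore = FALSE)
  b <- prediction_strength(d$m, d$labels, c("luminal", "basal"),
                           n_splits = 5, seed = 9, zscore = FALSE)
  expect_identical(a$ps_per_split, b$ps_per_split)
  tiny <- d$labels[c(1:3, 11:13)]
  expect_error(prediction_strength(d$m[, names(tiny)], tiny,
                                   c("luminal", "basal"), k = 2,
                                   zscore = FALSE),
               "at least 2\\*k")
})

test_that("posterior model priors, pooled covariance and shrinkage limits are exact", {
  # hand-computable toy: 2 features, 2 groups, 3 samples each
  m <- matrix(c(0, 0, 1, 1, 2, 2, 0, 1, 0, -1, 0, 0), 2,
              dimnames = list(c("f1", "f2"), paste0("S", 1:6)))
  labels <- stats::setNames(rep(c("luminal", "basal"), each = 3), colnames(m))
  mod <- fit_posterior_model(m, labels, shrinkage = 0)
  expect_equal(unname(mod$covariance),
               matrix(c(0.5, 0.5, 0.5, 1.0), 2), tolerance = 1e-12)
  expect_equal(unname(mod$priors), c(0.5, 0.5))
  expect_equal(unname(mod$means["luminal", ]), c(1, 1))

  mod_diag <- fit_posterior_model(m, labels, shrinkage = 1)
  expect_equal(unname(mod_diag$covariance),
               diag(c(0.5, 1.0)), tolerance = 1e-12)

  # priors are exactly the observed group frequencies
  lab3 <- stats::setNames(c(rep("luminal", 3), rep("basal", 2),
                            rep("double_negative", 5)), paste0("T", 1:10))
  m3 <- matrix(rnorm(20), 2, dimnames = list(c("f1", "f2"), names(lab3)))
  mod3 <- fit_posterior_model(m3, lab3)
  expect_equal(unname(mod3$priors[c("luminal", "basal", "double_negative")]),
               c(0.3, 0.2, 0.5))
})

test_that("posteriors are symmetric for identical groups and sharp for far means", {
  set.seed(10)
  base <- matrix(rnorm(5 * 10), 5)
  m <- cbind(base, base, base)
  dimnames(m) <- list(paste0("f", 1:5), sprintf("S%02d", 1:30))
  labels <- stats::setNames(rep(c("luminal", "basal", "double_negative"),
                                each = 10), colnames(m))
  post <- posterior_strengths(fit_posterior_model(m, labels), m)
  probs <- as.matrix(post[, c("luminal", "basal", "double_negative")])
  expect_true(all(abs(probs - 1 / 3) < 1e-9))

  d <- two_blob_matrix(n_per = 15, gap = 20, sd = 1)
  mod <- fit_posterior_model(d$m, d$labels)
  at_mean <- matrix(mod$means["luminal", ], ncol = 1,
                    dimnames = list(mod$features, "probe"))
  p <- posterior_strengths(mod, at_mean)
  expect_gt(p$luminal[1], 0.99)
  expect_true(p$strong[1])
})

test_that("posterior rows always sum to one and shifting features is absorbed by refit", {
  set.seed(12)
  d <- two_blob_matrix(n_per = 12, gap = 3, sd = 2)
  mod <- fit_posterior_model(d$m, d$labels)
  post <- posterior_strengths(mod, d$m)
  probs <- as.matrix(post[, c("luminal", "basal")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))

  shifted <- d$m + 5
  post2 <- posterior_strengths(fit_posterior_model(shifted, d$labels), shifted)
  expect_equal(post2$luminal, post$luminal, tolerance = 1e-9)
})

test_that("degenerate posterior inputs are rejected", {
  m <- matrix(rnorm(8), 2, dimnames = list(c("f1", "f2"), paste0("S", 1:4)))
  one <- stats::setNames(c("luminal", "luminal", "luminal", "basal"),
                         colnames(m))
  expect_error(fit_posterior_model(m, one), "single sample")
  m2 <- m
  m2[2, ] <- 7 # zero pooled variance
  lab <- stats::setNames(rep(c("luminal", "basal"), each = 2), colnames(m))
  expect_warning(mod <- fit_posterior_model(m2, lab), "zero-variance")
  expect_identical(mod$features, "f1")
})
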