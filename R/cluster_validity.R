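#' Cluster prediction strength between two subtypes
#'
#' Pools the samples of the two labels, repeatedly halves them at random into
#' training and test sets, fits k-means to each half, and evaluates
#' `ps(k) = min_j 1/(n_kj (n_kj - 1)) * sum_{i != i' in A_kj} D[...]_{ii'}`,
#' the minimum over test clusters of the proportion of sample pairs in a test
#' cluster that the nearest-training-centroid rule also co-assigns. For
#' k = 1 every pair is trivially co-assigned and each split scores 1.
#'
#' @param m feature-by-sample matrix; conventionally the z-scored marker-gene
#'   space used for subtype discovery (set `zscore = FALSE` if already scaled).
#' @param labels named subtype labels covering the matrix columns.
#' @param pair character vector of the two labels to compare.
#' @param k number of clusters (default 2).
#' @param n_splits number of random halvings (default 50).
#' @param seed RNG seed for the splits and k-means restarts.
#' @param zscore z-score rows of the pooled submatrix before clustering.
#' @return list of class `ps_result`: `pair`, `ps_per_split`, `ps_mean`.
#' @export
prediction_strength <- function(m, labels, pair, k = 2, n_splits = 50,
                                seed = 1, zscore = TRUE) {
  stopifnot(length(pair) == 2, k >= 1, n_splits >= 1)
  labels <- assert_samples_match(m, labels)
  keep <- names(labels)[labels %in% pair]
  cnt <- table(factor(labels[keep], pair))
  if (any(cnt < 2 * k))
    stop("each group of the pair needs at least 2*k samples; got ",
         paste(cnt, collapse = "/"))
  sub <- m[, keep, drop = FALSE]
  if (zscore) sub <- row_zscore(sub)
  X <- t(sub)
  n <- nrow(X)
  if (2 * k > floor(n / 2)) stop("k exceeds half-cohort size")

  set.seed(seed)
  ps <- vapply(seq_len(n_splits), function(s) {
    idx <- sample(n)
    tr <- idx[seq_len(floor(n / 2))]
    te <- idx[-seq_len(floor(n / 2))]
    if (k == 1) return(1)
    km_tr <- stats::kmeans(X[tr, , drop = FALSE], centers = k,
                           nstart = 10, iter.max = 300)
    km_te <- stats::kmeans(X[te, , drop = FALSE], centers = k,
                           nstart = 10, iter.max = 300)
    train_assign <- nearest_centroid(X[te, , drop = FALSE], km_tr$centers)
    props <- vapply(seq_len(k), function(j) {
      in_j <- km_te$cluster == j
      nj <- sum(in_j)
      if (nj < 2) return(NA_real_)
      tab <- table(train_assign[in_j])
      sum(tab * (tab - 1)) / (nj * (nj - 1))
    }, 0)
    if (all(is.na(props))) stop("every test cluster has fewer than 2 samples")
    if (anyNA(props)) warning("test cluster of size < 2 skipped")
    min(props, na.rm = TRUE)
  }, 0)

  structure(list(pair = pair, ps_per_split = ps, ps_mean = mean(ps)),
            class = "ps_result")
}

#' @export
print.ps_result <- function(x, ...) {
  cat(sprintf("<ps_result> %s vs %s: mean prediction strength %.3f over %d splits\n",
              x$pair[1], x$pair[2], x$ps_mean, length(x$ps_per_split)))
  invisible(x)
}

nearest_centroid <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Fit the Gaussian Bayes model behind per-sample subtype strength
#'
#' Group means, pooled within-group covariance (convexly shrunk toward its
#' diagonal), and frequency priors. The shrinkage intensity defaults to the
#' analytic estimate that minimizes the expected squared error of the
#' correlation estimate (Schafer-Strimmer), clipped to [0, 1]; it can be
#' overridden, e.g. `shrinkage = 1` for a diagonal model.
#'
#' @param m feature-by-sample matrix (e.g. z-scored marker genes).
#' @param labels named labels; every group needs >= 2 samples.
#' @param shrinkage optional fixed intensity in [0, 1].
#' @return list of class `posterior_model`: `features`, `groups`, `means`,
#'   `covariance`, `priors`, `shrinkage`.
#' @export
fit_posterior_model <- function(m, labels, shrinkage = NULL) {
  labels <- assert_samples_match(m, labels)
  groups <- intersect(SUBTYPES, unique(labels))
  if (length(groups) == 0) groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least 2 groups")
  cnt <- table(factor(labels, groups))
  if (any(cnt < 2)) stop("group with a single sample: ",
                         paste(names(cnt)[cnt < 2], collapse = ", "))

  X <- t(m)
  centered <- X
  means <- matrix(0, length(groups), ncol(X),
                  dimnames = list(groups, colnames(X)))
  for (g in groups) {
    rows <- labels == g
    means[g, ] <- colMeans(X[rows, , drop = FALSE])
    centered[rows, ] <- sweep(X[rows, , drop = FALSE], 2, means[g, ])
  }
  pooled_var <- colSums(centered^2) / (nrow(X) - length(groups))
  drop <- pooled_var <= .Machine$double.eps
  if (any(drop)) {
    warning("zero-variance features dropped: ",
            paste(colnames(X)[drop], collapse = ", "))
    centered <- centered[, !drop, drop = FALSE]
    means <- means[, !drop, drop = FALSE]
  }
  n <- nrow(centered)
  S <- crossprod(centered) / (n - length(groups))
  lambda <- if (is.null(shrinkage)) shrinkage_intensity(centered) else shrinkage
  lambda <- min(max(lambda, 0), 1)
  Sigma <- (1 - lambda) * S + lambda * diag(diag(S), nrow(S))

  priors <- stats::setNames(as.vector(cnt) / sum(cnt), groups)
  structure(list(features = colnames(centered), groups = groups, means = means,
                 covariance = Sigma, priors = priors, shrinkage = lambda),
            class = "posterior_model")
}

# analytic shrinkage of off-diagonal correlations toward zero:
# lambda* = sum Var(r_ij) / sum r_ij^2 over i != j (clipped later)
shrinkage_intensity <- function(centered) {
  n <- nrow(centered)
  p <- ncol(centered)
  if (p < 2 || n < 4) return(0)
  sdv <- sqrt(colSums(centered^2) / (n - 1))
  if (any(sdv == 0)) return(0)
  Z <- sweep(centered, 2, sdv, "/")
  R <- crossprod(Z) / (n - 1)
  W2_mean <- crossprod(Z^2) / n # mean of w_ij = z_i z_j products squared
  var_r <- n / ((n - 1)^3) * (n * W2_mean - (crossprod(Z) / n)^2 * n)
  off <- upper.tri(R)
  denom <- sum(R[off]^2)
  if (denom == 0) return(1)
  sum(var_r[off]) / denom
}

#' Per-sample Bayes posterior subtype strengths
#'
#' Evaluates `P(g = k | x) = f_k(x) P(k) / sum_k' f_k'(x) P(k')` with
#' `f_k` the Gaussian density at the group mean under the shared (shrunk)
#' covariance. Log densities are stabilized by subtracting the maximum
#' exponent before exponentiation. A posterior of at least 0.80 for the
#' assigned group is flagged as a strong prediction.
#'
#' @param model a `posterior_model`.
#' @param m feature-by-sample matrix containing the model features.
#' @return data.frame: sample, one probability column per group, `assigned`,
#'   `strong` (posterior of assigned group >= 0.80).
#' @export
posterior_strengths <- function(model, m) {
  missing <- setdiff(model$features, rownames(m))
  if (length(missing) > 0)
    stop("model features absent from matrix: ", paste(missing, collapse = ", "))
  X <- t(m[model$features, , drop = FALSE])
  ch <- tryCatch(chol(model$covariance),
                 error = function(e) stop("covariance not positive-definite: ", conditionMessage(e)))
  logdet <- 2 * sum(log(diag(ch)))
  loglik <- vapply(model$groups, function(g) {
    d <- sweep(X, 2, model$means[g, ])
    q <- colSums(backsolve(ch, t(d), transpose = TRUE)^2)
    -0.5 * (q + logdet) + log(model$priors[g])
  }, numeric(nrow(X)))
  loglik <- matrix(loglik, nrow = nrow(X),
                   dimnames = list(rownames(X), model$groups))
  stab <- loglik - apply(loglik, 1, max)
  post <- exp(stab) / rowSums(exp(stab))
  assigned <- model$groups[max.col(post, ties.method = "first")]
  out <- data.frame(sample = rownames(X), post, assigned = assigned,
                    strong = post[cbind(seq_len(nrow(post)),
                                        match(assigned, model$groups))] >= 0.80,
                    row.names = NULL, check.names = FALSE)
  out
}
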