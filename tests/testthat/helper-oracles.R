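# Independent oracles and small fixture builders shared across tests.

# Mann-Whitney U / (n1*n2), ties counted as half -- the AUC identity oracle.
auc_u_oracle <- function(scores, labels) {
  lum <- scores[labels == "luminal"]
  bas <- scores[labels == "basal"]
  u <- 0
  for (a in lum) for (b in bas) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(lum) * length(bas))
}

# Exhaustive cutoff oracle: evaluates misclassification at every midpoint
# between adjacent sorted unique scores (plus outside the range) and returns
# the minimum count achievable.
min_misclass_oracle <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(s[1] - 1, (utils::head(s, -1) + utils::tail(s, -1)) / 2, s[length(s)] + 1, s)
  lum <- scores[labels == "luminal"]
  bas <- scores[labels == "basal"]
  min(vapply(cands, function(c) sum(lum <= c) + sum(bas > c), 0))
}

misclass_at <- function(cutoff, scores, labels) {
  sum(scores[labels == "luminal"] <= cutoff) +
    sum(scores[labels == "basal"] > cutoff)
}

# Naive prediction-strength evaluation: same statistic, written as explicit
# loops over sample pairs, with its own split/k-means draws.
ps_naive_oracle <- function(X, k = 2, n_splits = 20, seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  mean(vapply(seq_len(n_splits), function(s) {
    idx <- sample(n)
    tr <- idx[seq_len(floor(n / 2))]
    te <- idx[-seq_len(floor(n / 2))]
    km_tr <- stats::kmeans(X[tr, , drop = FALSE], k, nstart = 10, iter.max = 300)
    km_te <- stats::kmeans(X[te, , drop = FALSE], k, nstart = 10, iter.max = 300)
    assign_tr <- apply(X[te, , drop = FALSE], 1, function(x)
      which.min(colSums((t(km_tr$centers) - x)^2)))
    props <- rep(NA_real_, k)
    for (j in seq_len(k)) {
      members <- which(km_te$cluster == j)
      if (length(members) < 2) next
      co <- 0
      for (a in members) for (b in members) if (a != b)
        co <- co + (assign_tr[a] == assign_tr[b])
      props[j] <- co / (length(members) * (length(members) - 1))
    }
    min(props, na.rm = TRUE)
  }, 0))
}

# Ridge-free logistic LOOCV oracle: per-case refit by direct optimization of
# the binomial log-likelihood (independent of the glm/IRLS path).
loocv_optim_oracle <- function(X, y) {
  nll <- function(b, X, y) {
    eta <- b[1] + X %*% b[-1]
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  n <- nrow(X)
  pred <- integer(n)
  for (i in seq_len(n)) {
    fit <- stats::optim(rep(0, ncol(X) + 1), nll, X = X[-i, , drop = FALSE],
                        y = y[-i], method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    p <- stats::plogis(fit$par[1] + sum(X[i, ] * fit$par[-1]))
    pred[i] <- as.integer(p > 0.5)
  }
  mean(pred == y)
}

# Small, clearly separated two-subtype cohort on the default panels.
toy_two_block_cohort <- function(n_per = 10, delta = 4, sd = 0.3, seed = 5) {
  panels <- default_panels()
  genes <- c(panels$luminal$genes, panels$basal$genes)
  samples <- c(sprintf("L%02d", seq_len(n_per)), sprintf("B%02d", seq_len(n_per)))
  labels <- stats::setNames(rep(c("luminal", "basal"), each = n_per), samples)
  set.seed(seed)
  m <- matrix(stats::rnorm(length(genes) * length(samples), 6, sd),
              length(genes), dimnames = list(genes, samples))
  m[panels$luminal$genes, labels == "luminal"] <-
    m[panels$luminal$genes, labels == "luminal"] + delta
  m[panels$basal$genes, labels == "basal"] <-
    m[panels$basal$genes, labels == "basal"] + delta
  attr(m, "expr_scale") <- "log_median_normalized"
  list(m = m, labels = labels, panels = panels)
}
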