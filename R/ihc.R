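#' Rule-based GATA3 / KRT5-6 immunohistochemistry classifier
#'
#' Encodes the reciprocal-staining logic read off routine sections: GATA3
#' positive with KRT5/6 at or below the positivity threshold is luminal,
#' the reverse is basal, both at or below the threshold is double-negative,
#' strong positivity for both (or intermediate positivity for both) is
#' noninformative. Scattered staining of the opposite marker in under 10% of
#' cells does not change a call.
#'
#' @param gata3,krt5_6 staining proportions in [0, 1] (GATA3 scored on
#'   nuclei, KRT5/6 on tumour tissue area).
#' @param pos_threshold positivity threshold (default 0.10).
#' @param strong_threshold strong-staining threshold (default 0.50).
#' @return list of class `ihc_call`: `call`, `rule`.
#' @export
rule_classify <- function(gata3, krt5_6, pos_threshold = 0.10,
                          strong_threshold = 0.50) {
  if (is.na(gata3) || is.na(krt5_6)) stop("GATA3 and KRT5/6 proportions are both required")
  stopifnot(gata3 >= 0, gata3 <= 1, krt5_6 >= 0, krt5_6 <= 1)
  if (gata3 > strong_threshold && krt5_6 > strong_threshold) {
    call <- "noninformative"; rule <- "strong positivity for both markers"
  } else if (gata3 > pos_threshold && krt5_6 <= pos_threshold) {
    call <- "luminal"; rule <- "GATA3 positive, KRT5/6 at most scattered"
  } else if (krt5_6 > pos_threshold && gata3 <= pos_threshold) {
    call <- "basal"; rule <- "KRT5/6 positive, GATA3 at most scattered"
  } else if (gata3 <= pos_threshold && krt5_6 <= pos_threshold) {
    call <- "double_negative"; rule <- "negative for both markers"
  } else {
    call <- "noninformative"; rule <- "intermediate positivity for both markers"
  }
  structure(list(call = call, rule = rule), class = "ihc_call")
}

#' Classify a table of IHC records
#'
#' @param records data.frame with columns `case`, `gata3`, `krt5_6`.
#' @param pos_threshold,strong_threshold see [rule_classify()].
#' @return data.frame: case, call, rule.
#' @export
classify_ihc <- function(records, pos_threshold = 0.10, strong_threshold = 0.50) {
  stopifnot(all(c("case", "gata3", "krt5_6") %in% colnames(records)))
  calls <- lapply(seq_len(nrow(records)), function(i)
    rule_classify(records$gata3[i], records$krt5_6[i],
                  pos_threshold, strong_threshold))
  data.frame(case = records$case,
             call = vapply(calls, `[[`, "", "call"),
             rule = vapply(calls, `[[`, "", "rule"),
             stringsAsFactors = FALSE)
}

#' Logistic-regression LOOCV accuracy of an IHC marker pair
#'
#' For each case the model `luminal ~ marker1 + marker2` is refit on the
#' remaining cases and the held-out case predicted at probability 0.5.
#' Double-negative cases must be excluded upstream. Complete separation is
#' handled by refitting with a small L2 ridge (1e-4) and a warning.
#'
#' @param records data.frame with a `case` column and the marker columns.
#' @param labels named labels ("luminal"/"basal") keyed by case id.
#' @param marker_pair two column names, default `c("gata3", "krt5_6")`.
#' @return list: `accuracy`, `predictions` (data.frame case, truth,
#'   predicted, p_luminal).
#' @export
lr_loocv <- function(records, labels, marker_pair = c("gata3", "krt5_6")) {
  stopifnot(length(marker_pair) == 2,
            all(marker_pair %in% colnames(records)))
  ids <- as.character(records$case)
  labels <- labels[ids]
  if (anyNA(labels)) stop("cases without labels: ",
                          paste(ids[is.na(labels)], collapse = ", "))
  if (!all(labels %in% c("luminal", "basal")))
    stop("lr_loocv expects luminal/basal labels only")
  if (length(unique(labels)) < 2) stop("single-class input")
  n <- nrow(records)
  if (n < 6) stop("need at least 6 cases for LOOCV")
  X <- as.matrix(records[, marker_pair])
  y <- as.integer(labels == "luminal")
  p_hat <- vapply(seq_len(n), function(i) {
    fit <- fit_logistic(X[-i, , drop = FALSE], y[-i])
    as.vector(stats::plogis(fit$intercept + X[i, ] %*% fit$beta))
  }, 0)
  pred <- ifelse(p_hat > 0.5, "luminal", "basal")
  list(accuracy = mean(pred == labels),
       predictions = data.frame(case = ids, truth = unname(labels),
                                predicted = pred, p_luminal = p_hat,
                                row.names = NULL))
}

# plain glm fit; on (quasi-)separation or non-convergence, ridge-penalized
# Newton iterations with lambda = 1e-4 on the slopes
fit_logistic <- function(X, y, ridge = 1e-4) {
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!separated && fit$converged)
    return(list(intercept = fit$coefficients[1], beta = fit$coefficients[-1]))
  warning("separation or non-convergence; refitting with L2 ridge ", ridge)
  Z <- cbind(1, X)
  pen <- diag(c(0, rep(ridge, ncol(X))))
  b <- numeric(ncol(Z))
  for (it in 1:100) {
    eta <- as.vector(Z %*% b)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(Z, y - p) - pen %*% b
    H <- crossprod(Z * w, Z) + pen
    step <- solve(H, grad)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  list(intercept = b[1], beta = b[-1])
}

#' Contingency summary of IHC calls against mRNA subtypes
#'
#' For each mRNA subtype, the count and nearest-integer percentage (halves
#' away from zero) of cases in each IHC call category, plus the overall
#' concordance (fraction of cases whose IHC call equals their mRNA subtype).
#'
#' @param calls data.frame with `case` and `call` columns (from
#'   [classify_ihc()]).
#' @param truth named mRNA subtype labels keyed by case id.
#' @return list: `table` (data.frame subtype, call, count, percent),
#'   `concordance`.
#' @export
contingency_summary <- function(calls, truth) {
  ids <- intersect(as.character(calls$case), names(truth))
  if (length(ids) == 0) stop("no case ids in common between calls and labels")
  unmatched <- setdiff(as.character(calls$case), names(truth))
  if (length(unmatched) > 0)
    stop("calls without matching labels: ", paste(unmatched, collapse = ", "))
  call_of <- stats::setNames(calls$call, calls$case)[ids]
  truth <- truth[ids]
  cats <- c("luminal", "basal", "double_negative", "noninformative")
  rows <- do.call(rbind, lapply(intersect(SUBTYPES, unique(truth)), function(g) {
    in_g <- truth == g
    cnt <- table(factor(call_of[in_g], cats))
    data.frame(subtype = g, call = cats, count = as.vector(cnt),
               percent = round_half_up(100 * as.vector(cnt) / sum(in_g)))
  }))
  list(table = rows, concordance = mean(call_of == truth))
}
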