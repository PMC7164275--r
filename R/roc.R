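#' Nonparametric AUC (Mann-Whitney statistic)
#'
#' The area under the empirical ROC curve for a continuous score against a
#' binary outcome, computed as the Mann-Whitney probability: the fraction
#' of case-control pairs in which the case scores higher, counting ties as
#' one half. Implemented via midranks, which is exactly equivalent to
#' exhaustive pair counting.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome (logical, or coercible to 0/1), `TRUE` =
#'   case; same length as `scores`.
#' @return the AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as_binary_labels(labels, length(scores))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop_rhino("degenerate", "both classes must be present (cases = %d, controls = %d)",
               n1, n0)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels, n) {
  if (length(labels) != n) {
    stop_rhino("input", "`scores` and `labels` must have equal length")
  }
  if (is.logical(labels)) return(labels)
  u <- sort(unique(labels))
  if (!all(labels %in% c(0, 1))) {
    stop_rhino("input", "`labels` must be logical or 0/1")
  }
  labels == 1
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from placement values:
#' per-case placements `V10` (mean over controls of the pairwise kernel)
#' and per-control placements `V01`, giving
#' `var(AUC) = var(V10)/n_case + var(V01)/n_control`, with a Wald interval
#' on the AUC scale clipped to `[0, 1]` and a two-sided p-value for
#' `H0: AUC = 0.5`. Depends on the scores only through ranks, so any
#' monotone transformation of the scores leaves the result unchanged.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome, `TRUE` = case; at least two of each class.
#' @param level confidence level; default 0.95.
#' @return an object of class `roc_result`: `auc`, `delong_se`, `ci95`
#'   (length-2 vector), `p_value`, `n_case`, `n_control`, `collapsed`
#'   (`TRUE` when the variance is exactly zero, e.g. perfect separation,
#'   and the interval degenerates to the point).
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- as_binary_labels(labels, length(scores))
  x <- scores[labels]   # cases
  y <- scores[!labels]  # controls
  m <- length(x)
  n <- length(y)
  if (m < 2 || n < 2) {
    stop_rhino("design", "need at least 2 cases and 2 controls (got %d, %d)", m, n)
  }
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - level) / 2)
  collapsed <- se == 0
  ci <- if (collapsed) c(auc, auc) else pmin(pmax(auc + c(-z, z) * se, 0), 1)
  p <- if (collapsed) {
    if (auc == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(auc - 0.5) / se)
  }
  structure(
    list(auc = auc, delong_se = se, ci95 = ci, level = level, p_value = p,
         n_case = m, n_control = n, collapsed = collapsed),
    class = "roc_result"
  )
}

#' Cross-validated AUC of a single predictor
#'
#' Stratified k-fold cross-validation of the raw predictor: no model is
#' fitted (a single variable already defines a ranking), so the held-out
#' AUC simply re-evaluates the Mann-Whitney statistic on each fold and the
#' mean over folds is returned. Folds are stratified by outcome so every
#' fold contains both classes; the split is deterministic given the seed.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome, `TRUE` = case.
#' @param folds number of folds; default 5.
#' @param seed fold-assignment seed; default 1.
#' @return mean held-out AUC, with per-fold values in attribute
#'   `"fold_auc"`.
#' @export
cross_validated_auc <- function(scores, labels, folds = 5, seed = 1) {
  labels <- as_binary_labels(labels, length(scores))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 < folds || n0 < folds) {
    stop_rhino("design",
               "cannot stratify %d folds: class sizes are %d cases and %d controls",
               folds, n1, n0)
  }
  set.seed(seed)
  fold <- integer(length(scores))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_auc <- vapply(seq_len(folds), function(f) {
    auc_mann_whitney(scores[fold == f], labels[fold == f])
  }, numeric(1))
  structure(mean(fold_auc), fold_auc = fold_auc)
}

#' @export
print.roc_result <- function(x, digits = 3, ...) {
  cat(sprintf("AUC = %.*f (DeLong SE %.*f), %d%% CI [%.*f, %.*f], p = %.4g\n",
              digits, x$auc, digits, x$delong_se, round(100 * x$level),
              digits, x$ci95[1], digits, x$ci95[2], x$p_value))
  invisible(x)
}
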