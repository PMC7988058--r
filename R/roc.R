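#' ROC analysis of one feature against a binary outcome
#'
#' AUC is computed by the rank (Mann-Whitney) identity with half credit for
#' ties. If the raw AUC -- the probability that a positive scores higher
#' than a negative -- is below 0.5, the reported direction flips to
#' `"low"` (low feature values indicate the positive class) and the AUC is
#' reported as \eqn{1 - AUC_{raw}}, so the reported AUC is always >= 0.5.
#' The cut-off maximises Youden's J (sensitivity + specificity - 1) over the
#' observed feature values, ties broken toward higher specificity; with
#' direction `"low"` a subject is called positive when its value is <= the
#' cut-off, with direction `"high"` when it is > the cut-off. The p-value
#' tests AUC = 0.5 through the tie-corrected normal approximation to the
#' Mann-Whitney statistic.
#'
#' @param scores numeric feature values.
#' @param labels binary outcome (1 = positive class, e.g. progressor).
#' @return object of class `roc_result`: `auc`, `direction`, `cutoff`,
#'   `sensitivity_pct`, `specificity_pct`, `p_value`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < 2L || n0 < 2L) {
    stop("ROC analysis needs at least two subjects in each class", call. = FALSE)
  }

  r <- rank(scores, ties.method = "average")
  auc_raw <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- if (auc_raw < 0.5) "low" else "high"
  auc <- if (direction == "low") 1 - auc_raw else auc_raw

  # tie-corrected normal approximation for U = auc_raw * n1 * n0
  N <- n1 + n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  var_u <- n1 * n0 / 12 * ((N + 1) - tie_term)
  p_value <- if (var_u <= 0) {
    1
  } else {
    z <- (auc_raw * n1 * n0 - n1 * n0 / 2) / sqrt(var_u)
    2 * stats::pnorm(-abs(z))
  }

  # Youden-optimal cut-off over observed values
  cand <- sort(unique(scores))
  if (direction == "low") {
    sens <- vapply(cand, function(c) mean(scores[labels == 1] <= c), 0)
    spec <- vapply(cand, function(c) mean(scores[labels == 0] > c), 0)
  } else {
    sens <- vapply(cand, function(c) mean(scores[labels == 1] > c), 0)
    spec <- vapply(cand, function(c) mean(scores[labels == 0] <= c), 0)
  }
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(spec[best])]

  structure(
    list(
      auc = auc, direction = direction, cutoff = cand[best],
      sensitivity_pct = 100 * sens[best], specificity_pct = 100 * spec[best],
      p_value = p_value, n_pos = n1, n_neg = n0
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  rule <- if (x$direction == "low") "<=" else ">"
  cat(sprintf(
    "<roc_result> AUC %.3f (P = %.3g), positive if value %s %.4g; sens %.1f%%, spec %.1f%% (n = %d+/%d-)\n",
    x$auc, x$p_value, rule, x$cutoff, x$sensitivity_pct, x$specificity_pct,
    x$n_pos, x$n_neg
  ))
  invisible(x)
}
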