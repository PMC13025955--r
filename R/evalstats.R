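## Evaluation statistics: threshold metrics, AUROC via the tie-corrected
## Mann-Whitney statistic, AUPRC by precision-recall step integration,
## DeLong's paired AUROC test on structural (midrank) components, and
## stratified percentile-bootstrap confidence intervals.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midranks, so ties count one half.
#'
#' @param y 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUROC in `[0, 1]`, or `NA` for single-class input.
#' @export
auroc <- function(y, scores) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration over distinct score thresholds (average-precision form):
#' `sum over thresholds of (recall step) * precision`.
#'
#' @inheritParams auroc
#' @return AUPRC, or `NA` for single-class input.
#' @export
auprc <- function(y, scores) {
  n1 <- sum(y == 1)
  if (n1 == 0L || all(y == 1)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)  # one operating point per threshold
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp); rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Threshold classification metrics with AUROC/AUPRC
#'
#' Confusion-matrix metrics at the given probability threshold plus the two
#' ranking areas. Ratios with zero denominators are reported as 0 and
#' flagged; single-class label vectors yield `NA` areas with a flag.
#'
#' @param y 0/1 vector.
#' @param scores numeric scores (probabilities for the threshold metrics).
#' @param threshold operating threshold (default 0.5; recorded in the
#'   report).
#' @return object of class `metrics_report`: list of `auroc`, `auprc`, `f1`,
#'   `precision`, `recall`, `specificity`, `threshold`, `n`, confusion
#'   counts and `flags`.
#' @export
classification_metrics <- function(y, scores, threshold = 0.5) {
  if (length(y) != length(scores) || length(y) == 0L)
    stopf("y and scores must be nonempty and of equal length")
  yhat <- as.integer(scores > threshold)
  tp <- sum(yhat == 1 & y == 1); fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1); tn <- sum(yhat == 0 & y == 0)
  flags <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); 0 } else num / den
  }
  prec <- ratio(tp, tp + fp, "precision_undefined")
  rec <- ratio(tp, tp + fn, "recall_undefined")
  spec <- ratio(tn, tn + fp, "specificity_undefined")
  f1 <- if (prec + rec == 0) { flags <- c(flags, "f1_undefined"); 0 }
        else 2 * prec * rec / (prec + rec)
  roc <- auroc(y, scores); prc <- auprc(y, scores)
  if (is.na(roc)) flags <- c(flags, "single_class")
  out <- list(auroc = roc, auprc = prc, f1 = f1, precision = prec,
              recall = rec, specificity = spec, threshold = threshold,
              n = length(y), tp = tp, fp = fp, fn = fn, tn = tn,
              flags = flags)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d @ threshold %.3f\n  AUROC %.4f  AUPRC %.4f\n  F1 %.4f  precision %.4f  recall %.4f  specificity %.4f\n",
    x$n, x$threshold, x$auroc, x$auprc, x$f1, x$precision, x$recall,
    x$specificity))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Youden-J optimal threshold
#'
#' Chooses the score threshold maximizing sensitivity + specificity - 1 on
#' (validation) data; useful when an explicit operating point is needed.
#'
#' @inheritParams auroc
#' @return scalar threshold.
#' @export
youden_threshold <- function(y, scores) {
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    yhat <- scores > t
    sum(yhat & y == 1) / sum(y == 1) + sum(!yhat & y == 0) / sum(y == 0) - 1
  }, 0)
  cand[which.max(j)]
}

## Structural components: V10[i] = P(score_i > score_neg) with ties = 1/2,
## via midranks (the O(n log n) formulation).
delong_components <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = sum(r_all[seq_len(m)]) / (m * n) - (m + 1) / (2 * n))
}

#' DeLong's test for two correlated AUROCs
#'
#' Compares the AUROCs of two score vectors for the same labels using the
#' structural-components (midrank) covariance estimate; two-sided normal
#' p-value.
#'
#' @param y 0/1 vector with both classes present.
#' @param scores_1,scores_2 paired score vectors.
#' @return list of class `delong_result`: `auc_1`, `auc_2`, `z`, `p_value`,
#'   `var_diff`.
#' @export
delong_test <- function(y, scores_1, scores_2) {
  if (length(unique(y)) < 2L) stopf("both classes required")
  c1 <- delong_components(y, scores_1)
  c2 <- delong_components(y, scores_2)
  m <- length(c1$v10); n <- length(c1$v01)
  s10 <- stats::var(c1$v10 - c2$v10)
  s01 <- stats::var(c1$v01 - c2$v01)
  vd <- s10 / m + s01 / n
  dauc <- c1$auc - c2$auc
  if (vd <= 0) {
    if (abs(dauc) < 1e-12) {
      z <- 0; p <- 1
    } else stopf("degenerate variance with unequal AUCs")
  } else {
    z <- dauc / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  out <- list(auc_1 = c1$auc, auc_2 = c2$auc, z = z, p_value = p,
              var_diff = vd)
  class(out) <- "delong_result"
  out
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong's test: AUC1 %.4f vs AUC2 %.4f, z = %.3f, p = %.4g\n",
              x$auc_1, x$auc_2, x$z, x$p_value))
  invisible(x)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately with replacement (so every
#' resample keeps both classes), recomputes the metric, and returns the
#' percentile interval.
#'
#' @param y 0/1 vector.
#' @param scores numeric scores.
#' @param metric `"auroc"` or `"auprc"`, or a function `(y, scores) ->
#'   scalar`.
#' @param n_boot bootstrap replicates (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return named vector `lower`, `upper` with attribute `point`.
#' @export
bootstrap_ci <- function(y, scores, metric = "auroc", n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  if (n_boot < 100L) stopf("'n_boot' must be >= 100")
  fn <- if (is.function(metric)) metric else switch(metric,
    auroc = auroc, auprc = auprc, stopf("unknown metric '%s'", metric))
  ip <- which(y == 1); ineg <- which(y == 0)
  stat <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ip, length(ip), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
    fn(y[idx], scores[idx])
  }, 0))
  a <- (1 - level) / 2
  ci <- stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
  structure(c(lower = ci[1], upper = ci[2]), point = fn(y, scores),
            n_boot = n_boot, level = level)
}
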