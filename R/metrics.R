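# Evaluation statistics: Pearson, MSE, ROC/PR AUC, bootstrap uncertainty,
# one-sided DeLong comparison of correlated ROC curves, cross-seed t-tests.

#' Pearson product-moment correlation
#'
#' @param pred,y numeric vectors of equal length (n >= 2), both with nonzero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson <- function(pred, y) {
  stopifnot(length(pred) == length(y), length(y) >= 2L)
  if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance input")
  }
  stats::cor(pred, y)
}

#' Mean squared error
#'
#' @param pred,y numeric vectors of equal length.
#' @return mean of squared residuals.
#' @export
mse <- function(pred, y) {
  stopifnot(length(pred) == length(y))
  if (length(y) == 0L) stop("empty input")
  mean((pred - y)^2)
}

#' Area under the ROC curve
#'
#' Computed with the midrank (Mann-Whitney) formula, so it equals the
#' probability that a random positive outscores a random negative, with ties
#' counting one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-linear) interpolation: walking down the score-sorted list,
#' the area is the sum over positives of precision-at-that-depth times the
#' recall increment. Tied scores are handled by averaging over the tie block.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels; at least one positive required.
#' @return area in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop("pr_auc needs at least one positive")
  # process tie groups in one step so the result is permutation-independent
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  s <- scores[o]
  blocks <- rle(s)
  n_cum <- cumsum(blocks$lengths)           # depth at each tie-block end
  tp_cum <- cumsum(lab)[n_cum]              # positives up to each block end
  tp_g <- diff(c(0, tp_cum))                # positives inside each block
  keep <- tp_g > 0
  # within a tie block precision is the precision at the block end
  sum((tp_cum[keep] / n_cum[keep]) * (tp_g[keep] / n1))
}

#' Bootstrap standard deviation of a metric
#'
#' SD of the metric over `B` paired resamples (with replacement) of
#' `(pred, y)`. Resamples on which the metric is undefined (e.g. one-class
#' labels for AUC) are redrawn.
#'
#' @param metric function of `(pred, y)` returning a scalar.
#' @param pred,y paired vectors.
#' @param B number of resamples (>= 100).
#' @param seed RNG seed.
#' @return bootstrap SD estimate.
#' @export
bootstrap_sd <- function(metric, pred, y, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L, length(pred) == length(y))
  set.seed(seed)
  n <- length(y)
  vals <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric(pred[idx], y[idx]), error = function(e) NULL)
      if (!is.null(v)) break
    }
    vals[b] <- v
  }
  stats::sd(vals)
}

# DeLong structural components: V10[i] = P(score_i > random negative) for
# positives, V01[j] likewise for negatives, ties counting one half.
.delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' One-sided DeLong test for paired ROC curves
#'
#' Tests H1: AUC(a) > AUC(b) for two score vectors over the same labels,
#' using the DeLong structural-components variance estimator for correlated
#' ROC curves. Identical score vectors give p = 0.5 (zero difference under a
#' symmetric null).
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary 0/1 labels, both classes present.
#' @return one-sided p-value.
#' @export
delong_one_sided <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  labels <- as.integer(labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("delong test needs >= 2 observations in each class")
  }
  if (all(scores_a == scores_b)) return(0.5)
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::var(ca$v10 - cb$v10)
  s01 <- stats::var(ca$v01 - cb$v01)
  v <- s10 / m + s01 / n
  d <- ca$auc - cb$auc
  if (!is.finite(v) || v <= 0) {
    # exact separation gives zero component variance; the comparison is
    # still decisive when the AUCs differ
    if (d > 0) return(0)
    if (d < 0) return(1)
    stop("degenerate DeLong variance")
  }
  stats::pnorm(d / sqrt(v), lower.tail = FALSE)
}

#' Two-sided t-test across per-seed metric values
#'
#' Compares the per-seed performance of two model variants (e.g. 20 or 50
#' matched-seed training runs each) with a two-sample t-test.
#'
#' @param metrics_a,metrics_b numeric vectors of per-seed metric values
#'   (>= 2 each).
#' @return two-sided p-value.
#' @export
seed_ttest <- function(metrics_a, metrics_b) {
  stopifnot(length(metrics_a) >= 2L, length(metrics_b) >= 2L)
  if (stats::sd(metrics_a) == 0 && stats::sd(metrics_b) == 0) {
    if (mean(metrics_a) == mean(metrics_b)) return(1.0)
    stop("zero pooled variance with unequal means")
  }
  stats::t.test(metrics_a, metrics_b)$p.value
}

#' Metric report with bootstrap uncertainty
#'
#' @param metric function of `(pred, y)`.
#' @param name metric name for the report.
#' @param pred,y paired vectors.
#' @param B bootstrap resamples.
#' @param seed RNG seed.
#' @return list: `metric`, `value`, `sd`, `B`.
#' @export
metric_report <- function(metric, name, pred, y, B = 1000L, seed = 1L) {
  list(metric = name, value = metric(pred, y),
       sd = bootstrap_sd(metric, pred, y, B = B, seed = seed), B = B)
}
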