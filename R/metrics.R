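#' Balanced accuracy
#'
#' Mean of sensitivity and specificity, the prevalence-corrected accuracy.
#' Both truth classes must be present.
#'
#' @param truth factor/logical of true labels; the second factor level (or
#'   `TRUE`) is the positive class.
#' @param pred predicted labels on the same coding.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  if (cc["tp"] + cc["fn"] == 0 || cc["tn"] + cc["fp"] == 0)
    stopf("balanced accuracy undefined: a truth class is absent")
  sens <- cc[["tp"]] / (cc[["tp"]] + cc[["fn"]])
  spec <- cc[["tn"]] / (cc[["tn"]] + cc[["fp"]])
  (sens + spec) / 2
}

as_binary <- function(x) {
  if (is.logical(x)) return(x)
  f <- as.factor(x)
  if (nlevels(f) > 2) stopf("labels must be binary (got %d levels)", nlevels(f))
  f == levels(f)[nlevels(f)]
}

#' Confusion counts for binary labels
#'
#' @inheritParams balanced_accuracy
#' @return Named vector `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, pred) {
  t1 <- as_binary(truth)
  # predictions coded on the truth's levels so class order is shared
  p1 <- if (is.logical(pred)) pred else
    as.factor(pred) == levels(as.factor(truth))[nlevels(as.factor(truth))]
  c(tp = sum(t1 & p1), fn = sum(t1 & !p1),
    tn = sum(!t1 & !p1), fp = sum(!t1 & p1))
}

#' Precision and recall of the positive class
#'
#' Precision is reported as 0 (flagged via attribute `undefined`) when no
#' positive predictions were made.
#'
#' @inheritParams balanced_accuracy
#' @return Scalar in `[0, 1]`.
#' @export
precision_score <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  denom <- cc[["tp"]] + cc[["fp"]]
  if (denom == 0) return(structure(0, undefined = TRUE))
  cc[["tp"]] / denom
}

#' @rdname precision_score
#' @export
recall_score <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  denom <- cc[["tp"]] + cc[["fn"]]
  if (denom == 0) stopf("recall undefined: no positive truth labels")
  cc[["tp"]] / denom
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic normalized by `n1 * n0`, with tied scores
#' averaged (midrank convention).
#'
#' @param scores numeric decision scores, larger = more positive.
#' @param truth binary truth labels (see [balanced_accuracy()]).
#' @return Scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  pos <- as_binary(truth)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("ROC AUC undefined: single-class labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Nadeau-Bengio corrected resampled paired t-test
#'
#' Compares two models' paired cross-validation score vectors coming from
#' identical splits. The naive resampled t-test is optimistic because
#' training sets overlap across splits; the correction inflates the variance
#' term by the train/test overlap factor `rho = n_test / n_train`:
#' `t = mean(d) / sqrt((1/n + rho) * var(d))` with `n = r * k` paired
#' differences and `df = n - 1`. For k-fold CV, `rho = 1 / (k - 1)`.
#'
#' @param scores_a,scores_b equal-length score vectors from the same splits.
#' @param k folds per repeat (used for `rho` unless `train_frac` is given).
#' @param r number of repeats (recorded; `r * k` must equal the vector
#'   length).
#' @param train_frac optional training fraction per split; `rho =
#'   (1 - train_frac) / train_frac`.
#' @return Object of class `comparison_result`: `t`, `df`, `p` (two-sided),
#'   `mean_diff`, `rho`, `var_diff`, plus a `degenerate` flag when the
#'   difference variance is zero.
#' @export
corrected_paired_ttest <- function(scores_a, scores_b, k = 10, r = 10,
                                   train_frac = NULL) {
  if (length(scores_a) != length(scores_b))
    stopf("paired score vectors differ in length (%d vs %d)",
          length(scores_a), length(scores_b))
  n <- length(scores_a)
  if (!is.null(r) && !is.null(k) && n != r * k)
    stopf("expected r * k = %d paired scores, got %d", r * k, n)
  rho <- if (!is.null(train_frac)) (1 - train_frac) / train_frac
         else 1 / (k - 1)
  d <- scores_a - scores_b
  md <- mean(d)
  vd <- stats::var(d)
  degenerate <- FALSE
  if (vd == 0) {
    degenerate <- TRUE
    if (md == 0) { t <- 0; p <- 1 } else { t <- sign(md) * Inf; p <- 0 }
  } else {
    t <- md / sqrt((1 / n + rho) * vd)
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  structure(list(t = t, df = n - 1L, p = p, mean_diff = md, rho = rho,
                 var_diff = vd, degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("corrected paired t-test: t(%d) = %.3f, p = %.4g, mean diff = %.4f (rho = %.3f)\n",
              x$df, x$t, x$p, x$mean_diff, x$rho))
  invisible(x)
}

#' Permutation test for a classification score
#'
#' Re-evaluates the full scoring procedure under `B` random permutations of
#' the class labels and reports the standard valid p-value
#' `(1 + #\{perm >= observed\}) / (B + 1)`.
#'
#' @param evaluator function taking a label vector and returning a scalar
#'   score; it must encapsulate the entire (selection + scoring) procedure on
#'   fixed splits.
#' @param labels the observed labels.
#' @param B number of permutations (>= 99 recommended for alpha = 0.05).
#' @param seed integer seed for the permutations.
#' @return Object of class `permutation_result`: `observed`, `perm_scores`,
#'   `p`, `B`, `seed`.
#' @export
permutation_test <- function(evaluator, labels, B = 999L, seed = 1L) {
  stopifnot(is.function(evaluator))
  if (B < 99) warnf("B = %d gives p-value resolution %.3f; alpha = 0.05 needs B >= 99",
                    B, 1 / (B + 1))
  observed <- evaluator(labels)
  perm_scores <- with_seed(seed, function() {
    vapply(seq_len(B), function(b) evaluator(sample(labels)), 0)
  })
  p <- (1 + sum(perm_scores >= observed)) / (B + 1)
  structure(list(observed = observed, perm_scores = perm_scores, p = p,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4f, p = %.4g (B = %d)\n",
              x$observed, x$p, x$B))
  invisible(x)
}
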