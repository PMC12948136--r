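# Classification metrics and the paired t-test used to compare models
# and experiments.

#' Confusion matrix
#'
#' Entry (i, j) counts samples with true class i predicted as class j
#' (0-based labels).
#'
#' @param true,predicted equal-length integer label vectors in
#'   `0..n_classes-1`.
#' @param n_classes number of classes.
#' @return n_classes x n_classes integer matrix with class labels as
#'   dimnames.
#' @export
confusion_matrix <- function(true, predicted, n_classes = 4L) {
  assert_that(length(true) == length(predicted), "label vectors differ in length")
  assert_that(length(true) > 0, "empty label vectors")
  lv <- 0:(n_classes - 1L)
  if (!all(true %in% lv) || !all(predicted %in% lv)) {
    stop(sprintf("labels must lie in 0..%d", n_classes - 1L), call. = FALSE)
  }
  m <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  m <- matrix(as.integer(m), n_classes, n_classes,
              dimnames = list(true = lv, predicted = lv))
  m
}

#' Accuracy and macro precision / recall / F1 from a confusion matrix
#'
#' Macro averages are unweighted means over classes.  A class never
#' predicted has undefined precision; it contributes 0 with a warning.
#'
#' @param confusion square count matrix (true x predicted).
#' @return list with `accuracy`, `precision`, `recall`, `f1` (macro),
#'   and per-class vectors `precision_class`, `recall_class`, `f1_class`.
#' @export
classification_metrics <- function(confusion) {
  assert_that(is.matrix(confusion) && nrow(confusion) == ncol(confusion),
              "confusion matrix must be square")
  tp <- diag(confusion)
  pred_tot <- colSums(confusion)
  true_tot <- rowSums(confusion)
  prec <- ifelse(pred_tot > 0, tp / pred_tot, NA_real_)
  if (anyNA(prec)) {
    warning("class(es) never predicted: precision undefined, counted as 0")
    prec[is.na(prec)] <- 0
  }
  rec <- ifelse(true_tot > 0, tp / true_tot, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / sum(confusion),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1),
       precision_class = prec, recall_class = rec, f1_class = f1)
}

#' Matthews correlation coefficient (multiclass)
#'
#' Uses the multiclass generalization (Gorodkin): 1 for a perfect
#' diagonal, about 0 for chance-level predictions.  Degenerate tables
#' (a single observed or predicted class) have an undefined MCC and
#' return `NaN` with a warning.
#'
#' @param confusion square count matrix.
#' @return value in `[-1, 1]`, or `NaN` for degenerate input.
#' @export
matthews_cc <- function(confusion) {
  assert_that(is.matrix(confusion) && nrow(confusion) == ncol(confusion),
              "confusion matrix must be square")
  C <- confusion
  n <- sum(C)
  trace <- sum(diag(C))
  pk <- colSums(C)  # predicted totals
  tk <- rowSums(C)  # true totals
  num <- trace * n - sum(tk * pk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  if (den == 0) {
    warning("MCC undefined: a single class present in truth or prediction")
    return(NaN)
  }
  num / den
}

#' One-vs-rest ROC AUC per class
#'
#' Trapezoidal (rank-based) AUC of each class's predicted probability
#' against the binary indicator of that class.  Classes absent from the
#' truth get `NaN` with a warning.
#'
#' @param true integer labels (0-based).
#' @param prob matrix (n x n_classes) of class probabilities, rows
#'   summing to 1.
#' @return named numeric vector of per-class AUCs.
#' @export
roc_auc_ovr <- function(true, prob) {
  assert_that(is.matrix(prob) && nrow(prob) == length(true),
              "probability matrix does not match labels")
  assert_that(max(abs(rowSums(prob) - 1)) < 1e-6,
              "probability rows must sum to 1")
  n_classes <- ncol(prob)
  out <- vapply(seq_len(n_classes), function(j) {
    pos <- true == (j - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NaN)
    # Mann-Whitney formulation == trapezoidal area under the ROC curve
    r <- rank(prob[, j], ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  if (anyNA(out)) warning("class(es) absent from the truth: AUC is NaN")
  names(out) <- paste0("class_", 0:(n_classes - 1L))
  out
}

#' Paired t-test
#'
#' The statistic is `t = mean(d) / (sd(d) / sqrt(n))` over the paired
#' differences `d = a - b`, with the sample standard deviation
#' (n - 1 denominator); the two-sided p-value comes from the t
#' distribution with n - 1 degrees of freedom.  Identical pairs give a
#' zero standard deviation: the statistic is then infinite (or NaN when
#' the mean difference is also zero) and flagged.
#'
#' @param a,b equal-length numeric vectors of paired observations
#'   (n >= 2).
#' @return A `t_test_result`: list with `mean_diff`, `sd_diff`, `n`,
#'   `statistic`, `df`, `p_value` and `degenerate`.
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 1, 1))  # t = 2 * sqrt(3)
#' @export
paired_t_test <- function(a, b) {
  assert_that(length(a) == length(b), "paired vectors differ in length")
  n <- length(a)
  if (n < 2) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sd_d <- stats::sd(d)
  degenerate <- sd_d == 0
  if (degenerate) {
    if (md == 0) {
      # identical vectors: no evidence of a difference
      t_stat <- 0
      p <- 1
    } else {
      warning("all paired differences identical: t statistic is infinite")
      t_stat <- sign(md) * Inf
      p <- 0
    }
  } else {
    t_stat <- md / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(mean_diff = md, sd_diff = sd_d, n = n,
                 statistic = t_stat, df = n - 1L, p_value = p,
                 degenerate = degenerate),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf(
    "<t_test_result> mean diff %.4g (sd %.4g, n %d): t = %.4g, p = %.4g\n",
    x$mean_diff, x$sd_diff, x$n, x$statistic, x$p_value))
  invisible(x)
}

#' Per-fold metrics report
#'
#' Bundles per-fold metrics with mean +/- sd aggregates and the summed
#' confusion matrix (raw and row-normalized).
#'
#' @param fold_metrics data.frame with one row per fold (columns
#'   `fold`, `accuracy`, `precision`, `recall`, `f1`, `mcc`, plus
#'   optional AUC columns).
#' @param confusion summed confusion matrix over folds.
#' @return A `metrics_report`.
#' @export
metrics_report <- function(fold_metrics, confusion) {
  num <- fold_metrics[, setdiff(names(fold_metrics), "fold"), drop = FALSE]
  agg <- data.frame(metric = names(num),
                    mean = vapply(num, mean, numeric(1), na.rm = TRUE),
                    sd = vapply(num, stats::sd, numeric(1), na.rm = TRUE))
  rownames(agg) <- NULL
  norm <- sweep(confusion, 1L, pmax(rowSums(confusion), 1L), `/`)
  structure(list(folds = fold_metrics, summary = agg,
                 confusion = confusion, confusion_normalized = norm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  f1 <- x$summary[x$summary$metric == "f1", ]
  cat(sprintf("<metrics_report> %d folds, macro F1 %.3f +/- %.3f\n",
              nrow(x$folds), f1$mean, f1$sd))
  invisible(x)
}

#' Pairwise paired t-tests between models
#'
#' Pairs per-fold F1 scores of every pair of models, the style of
#' model-to-model and experiment-to-experiment comparison heatmaps.
#'
#' @param fold_f1 named list: model -> numeric vector of per-fold F1
#'   scores (equal lengths).
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, matching the unadjusted protocol; `"holm"`
#'   available).
#' @return data.frame `model_a`, `model_b`, `t`, `p_value`, `p_adjusted`.
#' @export
pairwise_model_ttests <- function(fold_f1, adjust = "none") {
  nm <- names(fold_f1)
  assert_that(length(nm) >= 2, "need at least two models")
  combs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    tt <- suppressWarnings(paired_t_test(fold_f1[[a]], fold_f1[[b]]))
    data.frame(model_a = a, model_b = b, t = tt$statistic,
               p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out
}
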