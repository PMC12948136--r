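test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), n_classes = 2)
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2))
  perfect <- confusion_matrix(0:3, 0:3, 4)
  expect_equal(unname(perfect), diag(1L, 4))
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 4), "labels must lie")
})

test_that("macro metrics match a hand-computed table", {
  cm <- matrix(c(1, 0, 1, 2), 2, 2)  # true x predicted
  m <- classification_metrics(cm)
  expect_equal(m$precision_class, c(1, 2 / 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m$recall_class, c(0.5, 1), ignore_attr = TRUE)
  expect_equal(m$f1, (2 / 3 + 4 / 5) / 2, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.75)
  pd <- classification_metrics(diag(3L) * 5L)
  expect_equal(unlist(pd[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # all mass in one predicted column over balanced classes
  one_col <- matrix(c(5, 5, 0, 0), 2, 2)
  expect_warning(mo <- classification_metrics(one_col), "never predicted")
  expect_equal(mo$accuracy, 0.5)
  expect_error(classification_metrics(matrix(0, 2, 3)), "square")
})

test_that("metric macro-averages are invariant to class relabelling", {
  set.seed(31)
  true <- sample(0:3, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, true, sample(0:3, 200, replace = TRUE))
  m1 <- classification_metrics(confusion_matrix(true, pred, 4))
  perm <- c(2L, 0L, 3L, 1L)
  m2 <- classification_metrics(confusion_matrix(perm[true + 1], perm[pred + 1], 4))
  expect_equal(m1$f1, m2$f1, tolerance = 1e-12)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(sort(unname(m1$precision_class)), sort(unname(m2$precision_class)),
               tolerance = 1e-12)
})

test_that("Matthews correlation matches the binary formula and its limits", {
  cm <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(matthews_cc(cm), 1 / 3, tolerance = 1e-12)
  expect_equal(matthews_cc(diag(7L, 4)), 1)
  expect_warning(v <- matthews_cc(matrix(c(3, 0, 2, 0), 2, 2)), "undefined")
  expect_true(is.nan(v))
  # independence: MCC near zero at large n
  set.seed(5)
  a <- sample(0:3, 4000, replace = TRUE)
  b <- sample(0:3, 4000, replace = TRUE)
  expect_lt(abs(matthews_cc(confusion_matrix(a, b, 4))), 0.05)
})

test_that("one-vs-rest AUC behaves at its extremes and under independence", {
  prob <- function(score) cbind(score, 1 - score)
  y <- c(0, 0, 1, 1)
  expect_equal(unname(roc_auc_ovr(y, prob(c(0.9, 0.8, 0.2, 0.1)))[1]), 1)
  expect_equal(unname(roc_auc_ovr(y, prob(c(0.1, 0.2, 0.8, 0.9)))[1]), 0)
  set.seed(6)
  n <- 4000
  s <- runif(n)
  yy <- sample(0:1, n, replace = TRUE)
  expect_lt(abs(roc_auc_ovr(yy, prob(s))[[1]] - 0.5), 0.04)
  expect_warning(a <- roc_auc_ovr(c(0, 0), prob(c(0.2, 0.4))), "absent")
  expect_true(is.nan(a[[2]]))
  # cross-check against an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(7)
  sc <- runif(50)
  yb <- sample(0:1, 50, replace = TRUE)
  ref <- as.numeric(suppressMessages(pROC::auc(yb, sc)))
  expect_equal(roc_auc_ovr(yb, prob(sc))[[2]], ref, tolerance = 1e-12)
})

test_that("the paired t statistic follows its definition", {
  r <- paired_t_test(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
  expect_equal(r$mean_diff, 2)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  # oracle: one-sample t-test on the differences
  ref <- stats::t.test(c(1, 2, 3))
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  same <- paired_t_test(c(1, 2), c(1, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_warning(deg <- paired_t_test(c(2, 3, 4), c(1, 2, 3)), "infinite")
  expect_true(is.infinite(deg$statistic) && deg$statistic > 0)
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("type-I error is controlled under a simulated null", {
  set.seed(123)
  reps <- 500
  hits <- 0
  for (i in seq_len(reps)) {
    a <- rnorm(10)
    b <- rnorm(10)
    if (paired_t_test(a, b)$p_value < 0.05) hits <- hits + 1
  }
  rate <- hits / reps
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.12)
})

test_that("pairwise model comparisons assemble a full table", {
  f1 <- list(a = c(0.9, 0.92, 0.91), b = c(0.8, 0.82, 0.81),
             c = c(0.85, 0.86, 0.84))
  tt <- pairwise_model_ttests(f1)
  expect_equal(nrow(tt), 3L)
  expect_equal(tt$p_value, tt$p_adjusted)  # no correction by default
  tth <- pairwise_model_ttests(f1, adjust = "holm")
  expect_true(all(tth$p_adjusted >= tth$p_value))
})
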