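test_that("standardization maps to zero mean / unit variance with guards", {
  expect_equal(standardize(matrix(c(1, 3), 2, 1)),
               matrix(c(-1, 1) / stats::sd(c(1, 3)), 2, 1))
  # constant channel collapses to zero through the epsilon guard
  expect_equal(standardize(matrix(5, 3, 1)), matrix(0, 3, 1))
  expect_error(standardize(matrix(numeric(0), 0, 1)), "zero-length")
})

test_that("train-fitted statistics do not recentre the test partition", {
  cohort <- small_cohort()
  std <- standardize_trials(cohort$trials[1:8],
                            stats_trials = cohort$trials[1:4])
  # training side: per-channel mean ~ 0 over unpadded frames
  tr_rows <- do.call(rbind, lapply(std$trials[1:4], function(t) {
    t$markers[seq_len(t$true_length[["markers"]]), ]
  }))
  expect_lt(max(abs(colMeans(tr_rows))), 1e-10)
  expect_lt(max(abs(apply(tr_rows, 2, sd) - 1)), 1e-10)
  # held-out side keeps a non-zero offset in general
  te_rows <- do.call(rbind, lapply(std$trials[5:8], function(t) {
    t$markers[seq_len(t$true_length[["markers"]]), ]
  }))
  expect_gt(max(abs(colMeans(te_rows))), 1e-4)
  # padding zeros survive standardization untouched
  t1 <- std$trials[[1]]
  n <- t1$true_length[["markers"]]
  expect_true(all(t1$markers[(n + 1):585, ] == 0))
})

test_that("standardization is idempotent on its statistics source", {
  x <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  s1 <- standardize(x)
  expect_equal(standardize(s1), s1, tolerance = 1e-12)
})

test_that("zero-padding appends zeros and rejects shrinking", {
  x <- matrix(1:6, 3, 2)
  p <- zero_pad(x, 5)
  expect_equal(dim(p), c(5L, 2L))
  expect_equal(p[1:3, ], x)
  expect_true(all(p[4:5, ] == 0))
  expect_identical(zero_pad(x, 3), x)
  expect_error(zero_pad(matrix(0, 586, 2), 585), "shorter")
})

test_that("sample-wise 10-fold plan partitions and stratifies", {
  labels <- data.frame(trial_id = sprintf("t%03d", 1:100),
                       subject_id = rep(1:25, each = 4),
                       class = rep(0:3, 25))
  plan <- split_samples_kfold(labels, k = 10, seed = 4)
  tests <- lapply(plan$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:100)
  expect_true(all(lengths(tests) == 10L))
  for (fold in plan$folds) {
    expect_length(intersect(fold$train, fold$test), 0)
    expect_length(intersect(fold$val, fold$test), 0)
    expect_length(intersect(fold$train, fold$val), 0)
    # stratified: each class nearly equally represented in each test fold
    tab <- table(factor(labels$class[fold$test], levels = 0:3))
    expect_true(all(tab >= 2 & tab <= 3))
  }
  # k dividing the per-class counts: perfectly class-balanced test folds
  lab4 <- data.frame(trial_id = sprintf("u%02d", 1:32),
                     subject_id = rep(1:8, each = 4), class = rep(0:3, 8))
  p4 <- split_samples_kfold(lab4, k = 4, seed = 9, val_fraction = 0)
  for (fold in p4$folds) {
    expect_equal(as.vector(table(factor(lab4$class[fold$test], levels = 0:3))),
                 rep(2L, 4))
  }
  plan2 <- split_samples_kfold(labels, k = 10, seed = 4)
  expect_identical(plan, plan2)
  expect_error(split_samples_kfold(labels[1:5, ], k = 10), "exceeds")
})

test_that("subject-wise folds reserve whole subjects and stay disjoint", {
  cohort_labels <- data.frame(
    trial_id = sprintf("t%03d", 1:200),
    subject_id = rep(1:50, each = 4),
    class = rep(0:3, 50))
  p3 <- split_subjects_kfold(cohort_labels, n_test_subjects = 10, k = 5,
                             seed = 2)
  expect_equal(p3$experiment, 3L)
  test_subj <- lapply(p3$folds, `[[`, "test_subjects")
  expect_equal(sort(unlist(test_subj)), 1:50)  # partition of all subjects
  expect_no_subject_overlap(p3, cohort_labels)
  p2 <- split_subjects_kfold(cohort_labels, n_test_subjects = 5, k = 5,
                             seed = 2)
  expect_equal(p2$experiment, 2L)
  subj2 <- unlist(lapply(p2$folds, `[[`, "test_subjects"))
  expect_equal(length(subj2), 25L)
  expect_equal(anyDuplicated(subj2), 0L)
  expect_no_subject_overlap(p2, cohort_labels)
  expect_error(split_subjects_kfold(cohort_labels, n_test_subjects = 20,
                                    k = 5, seed = 1), "disjoint")
  # overlap allowed when requested
  pov <- split_subjects_kfold(cohort_labels, n_test_subjects = 20, k = 5,
                              seed = 1, disjoint = FALSE)
  expect_no_subject_overlap(pov, cohort_labels)
})

test_that("datasets round-trip losslessly through the CSV container", {
  cohort <- generate_cohort(2, 1, seed = 21)
  dir <- file.path(tempdir(), "gxds")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  write_dataset(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_dataset(dir)
  expect_length(back$trials, 8L)
  for (i in c(1, 8)) {
    for (m in c("markers", "grf", "emg", "fm")) {
      expect_equal(back$trials[[i]][[m]], cohort$trials[[i]][[m]])
    }
    expect_equal(back$trials[[i]]$speed_class, cohort$trials[[i]]$speed_class)
    expect_equal(back$trials[[i]]$true_length, cohort$trials[[i]]$true_length)
  }
  # tampered manifest: shrink the expected EMG channel count
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  man$modalities$spatial[man$modalities$name == "emg"] <- 7L
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_dataset(dir), "emg.*expected 8985 x 7")
  expect_error(load_dataset(file.path(tempdir(), "no_such_dir")),
               "does not exist")
  empty <- file.path(tempdir(), "gxds_empty")
  dir.create(empty, showWarnings = FALSE)
  expect_error(load_dataset(empty), "manifest")
})
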