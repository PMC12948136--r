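# Cross-validation split protocols.
#
# Experiment 1: sample-wise stratified 10-fold CV with reshuffling.
# Experiments 2 and 3: subject-wise k-fold CV reserving a fixed number of
# subjects per fold for testing (5 and 10 respectively), so that no
# subject contributes trials to both sides of a fold.

new_split_plan <- function(experiment, unit, k, seed, folds) {
  structure(list(experiment = experiment, unit = unit, k = k,
                 seed = as.integer(seed), folds = folds),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> experiment %d, %s-wise, %d folds (seed %d)\n",
              x$experiment, x$unit, x$k, x$seed))
  invisible(x)
}

# stratified assignment of indices to k folds under a derived seed
stratified_fold_ids <- function(class, k, seed) {
  fold_of <- integer(length(class))
  offset <- 0L
  for (cl in sort(unique(class))) {
    idx <- which(class == cl)
    idx <- with_seed(derive_seed(seed, 7, cl), sample(idx))
    # rotate the fold sequence between classes so remainders spread out
    # and fold sizes stay balanced
    fold_of[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold_of
}

# carve a stratified validation slice out of a training index set
carve_validation <- function(train, class, val_fraction, seed) {
  if (val_fraction <= 0) return(list(train = train, val = integer(0)))
  val <- integer(0)
  for (cl in unique(class[train])) {
    idx <- train[class[train] == cl]
    n_val <- max(1L, round(val_fraction * length(idx)))
    if (n_val >= length(idx)) n_val <- length(idx) - 1L
    if (n_val > 0) {
      val <- c(val, with_seed(derive_seed(seed, 13, cl),
                              sample(idx, n_val)))
    }
  }
  list(train = setdiff(train, val), val = sort(val))
}

#' Sample-wise stratified k-fold split (Experiment 1)
#'
#' Every trial appears in exactly one test fold; folds are stratified by
#' class.  A validation slice (default 10%, stratified) is carved out of
#' each fold's training portion.  One seed fixes the whole plan; per-fold
#' shuffles are deterministic sub-streams of it.
#'
#' @param labels data.frame with columns `trial_id`, `subject_id`, `class`.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param val_fraction fraction of the training portion held out for
#'   validation-based early stopping.
#' @return A `split_plan` whose `folds` are lists with integer index
#'   vectors `train`, `val`, `test` (rows of `labels`).
#' @export
split_samples_kfold <- function(labels, k = 10L, seed = 1L,
                                val_fraction = 0.1) {
  n <- nrow(labels)
  assert_that(is_count(k) && k >= 2, "k must be an integer >= 2")
  if (k > n) stop(sprintf("k = %d exceeds the number of samples (%d)", k, n),
                  call. = FALSE)
  fold_of <- stratified_fold_ids(labels$class, k, seed)
  folds <- lapply(seq_len(k), function(i) {
    test <- which(fold_of == i)
    rest <- which(fold_of != i)
    cv <- carve_validation(rest, labels$class, val_fraction,
                           derive_seed(seed, 17, i))
    list(train = sort(cv$train), val = cv$val, test = sort(test))
  })
  new_split_plan(1L, "sample", k, seed, folds)
}

#' Subject-wise k-fold split (Experiments 2 and 3)
#'
#' Reserves `n_test_subjects` subjects per fold for testing; all trials of
#' a subject stay on one side of every fold.  By default the test subject
#' sets are pairwise disjoint across folds (which requires
#' `n_test_subjects * k <= n_subjects`); set `disjoint = FALSE` to draw an
#' independent random subject set per fold instead.
#'
#' @inheritParams split_samples_kfold
#' @param n_test_subjects number of held-out test subjects per fold
#'   (5 for Experiment 2, 10 for Experiment 3).
#' @param k number of folds (default 5).
#' @param disjoint whether fold test sets partition the subject pool.
#' @return A `split_plan`; each fold additionally records `test_subjects`.
#' @export
split_subjects_kfold <- function(labels, n_test_subjects, k = 5L, seed = 1L,
                                 val_fraction = 0.1, disjoint = TRUE) {
  assert_that(is_count(k) && is_count(n_test_subjects),
              "k and n_test_subjects must be positive integers")
  subjects <- sort(unique(labels$subject_id))
  n_subj <- length(subjects)
  if (disjoint && n_test_subjects * k > n_subj) {
    stop(sprintf(
      "disjoint test sets need n_test_subjects * k <= %d subjects (got %d x %d)",
      n_subj, n_test_subjects, k), call. = FALSE)
  }
  if (!disjoint && n_test_subjects >= n_subj) {
    stop("n_test_subjects must leave at least one training subject",
         call. = FALSE)
  }
  shuffled <- with_seed(derive_seed(seed, 23), sample(subjects))
  folds <- lapply(seq_len(k), function(i) {
    test_subj <- if (disjoint) {
      shuffled[((i - 1L) * n_test_subjects + 1L):(i * n_test_subjects)]
    } else {
      with_seed(derive_seed(seed, 23, i), sample(subjects, n_test_subjects))
    }
    rest_subj <- setdiff(subjects, test_subj)
    n_val_subj <- max(1L, round(val_fraction * length(rest_subj)))
    val_subj <- with_seed(derive_seed(seed, 29, i),
                          sample(rest_subj, n_val_subj))
    train_subj <- setdiff(rest_subj, val_subj)
    list(train = which(labels$subject_id %in% train_subj),
         val = which(labels$subject_id %in% val_subj),
         test = which(labels$subject_id %in% test_subj),
         test_subjects = sort(test_subj))
  })
  experiment <- if (n_test_subjects >= 10L) 3L else 2L
  new_split_plan(experiment, "subject", k, seed, folds)
}

#' Serialize a split plan to JSON for audit
#'
#' @param plan a `split_plan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
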