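# End-to-end experiment runner: cohort -> splits -> per-fold training and
# metrics -> model comparisons -> relevance aggregation -> analyzer
# comparison by perturbation.

#' Cross-validate one model specification over a split plan
#'
#' Fits the model on every fold's training partition (statistics fitted
#' on the training trials only and applied everywhere), evaluates on the
#' fold's test partition and aggregates accuracy, macro
#' precision/recall/F1, MCC and mean one-vs-rest AUC.  Folds whose
#' training partition misses a class are skipped with a warning.
#'
#' @param spec a [model_spec()] (neural or baseline family).
#' @param cohort a `gait_cohort`.
#' @param plan a `split_plan`.
#' @param train_cfg a [train_config()] (ignored for baselines).
#' @param decimate per-modality temporal decimation applied to neural
#'   inputs (see [stack_inputs()]); baseline families instead use the
#'   `flatten_decimate` / `n_pc` / `regularize` entries of `spec$hyper`.
#' @param seed base seed; per-fold model initialisation seeds derive
#'   from it.
#' @return list with `report` (a `metrics_report`), `fold_f1` and
#'   `models` (per-fold fitted models or baselines).
#' @export
cross_validate <- function(spec, cohort, plan, train_cfg = train_config(),
                           decimate = NULL, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(plan, "split_plan"))
  labels <- cohort$labels
  n_classes <- length(unique(labels$class))
  is_nn <- spec$family %in% nn_families
  fold_rows <- list()
  conf_sum <- matrix(0L, n_classes, n_classes)
  models <- list()
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    y_train <- labels$class[fold$train]
    if (length(unique(y_train)) < n_classes) {
      warning(sprintf("fold %d: class missing from training; skipped", fi))
      next
    }
    std <- standardize_trials(cohort$trials,
                              stats_trials = cohort$trials[fold$train])
    tr <- std$trials
    if (is_nn) {
      hyper <- spec$hyper
      if (!is.null(decimate) && is.null(hyper$shapes)) {
        hyper$shapes <- decimated_shapes(decimate)
      }
      sp <- model_spec(spec$family, spec$modalities, hyper)
      net <- build_model(sp, n_classes = n_classes,
                         seed = derive_seed(seed, 211, fi))
      cfg <- train_cfg
      cfg$seed <- derive_seed(seed, 223, fi)
      x_train <- stack_inputs(tr[fold$train], decimate = decimate)
      x_val <- if (length(fold$val)) {
        stack_inputs(tr[fold$val], decimate = decimate)
      } else {
        NULL
      }
      train_network(net, x_train, y_train,
                    val_inputs = x_val, val_y = labels$class[fold$val],
                    config = cfg)
      prob <- predict_proba(net, stack_inputs(tr[fold$test],
                                              decimate = decimate))
      models[[fi]] <- net
    } else {
      hyper <- utils::modifyList(
        list(flatten_decimate = 16L, n_pc = 50L, regularize = 0),
        spec$hyper)
      ftr <- flatten_trials(tr[fold$train], spec$modalities,
                            hyper$flatten_decimate)
      fte <- flatten_trials(tr[fold$test], spec$modalities,
                            hyper$flatten_decimate)
      if (!is.null(hyper$n_pc) && hyper$n_pc > 0 &&
          hyper$n_pc < ncol(ftr)) {
        pc <- stats::prcomp(ftr, center = TRUE, scale. = FALSE,
                            rank. = min(hyper$n_pc, nrow(ftr) - 1L))
        ftr <- pc$x
        fte <- scale(fte, center = pc$center, scale = FALSE) %*% pc$rotation
      }
      fit <- fit_baseline(spec$family, ftr, y_train,
                          regularize = hyper$regularize)
      prob <- predict(fit, fte, type = "prob")
      prob <- prob[, as.character(0:(n_classes - 1L)), drop = FALSE]
      models[[fi]] <- fit
    }
    y_test <- labels$class[fold$test]
    pred <- max.col(prob) - 1L
    cm <- confusion_matrix(y_test, pred, n_classes)
    met <- classification_metrics(cm)
    auc <- suppressWarnings(roc_auc_ovr(y_test, prob))
    fold_rows[[fi]] <- data.frame(
      fold = fi, accuracy = met$accuracy, precision = met$precision,
      recall = met$recall, f1 = met$f1,
      mcc = suppressWarnings(matthews_cc(cm)),
      auc_macro = mean(auc, na.rm = TRUE))
    conf_sum <- conf_sum + cm
  }
  fold_metrics <- do.call(rbind, fold_rows)
  assert_that(!is.null(fold_metrics), "no usable folds")
  list(report = metrics_report(fold_metrics, conf_sum),
       fold_f1 = fold_metrics$f1, models = models)
}

#' Experiment configuration
#'
#' @param models named list of [model_spec()]s.
#' @param experiment 1 (sample-wise 10-fold), 2 (subject-wise, 5 test
#'   subjects per fold) or 3 (subject-wise, 10 test subjects per fold).
#' @param n_subjects,trials_per_subject_per_class cohort size.
#' @param k number of folds (defaults: 10 for experiment 1, 5 otherwise).
#' @param train a [train_config()].
#' @param decimate per-modality temporal decimation for neural inputs.
#' @param analyzers analyzers for the perturbation comparison (see
#'   [compare_analyzers()]).
#' @param window,morf_steps,n_explain perturbation window, steps and the
#'   number of test samples explained.
#' @param seed master seed; every stage derives sub-seeds from it.
#' @param out_dir output directory for run artifacts (`NULL`: a fresh
#'   directory under `tempdir()`).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(models, experiment = 1L, n_subjects = 50L,
                              trials_per_subject_per_class = 1L, k = NULL,
                              train = train_config(), decimate = NULL,
                              analyzers = list(lrp = "lrp_epsilon",
                                               random = "random"),
                              window = c(7L, 7L), morf_steps = 20L,
                              n_explain = 20L, seed = 1L, out_dir = NULL) {
  assert_that(experiment %in% 1:3, "experiment must be 1, 2 or 3")
  if (is.null(k)) k <- if (experiment == 1L) 10L else 5L
  structure(list(models = models, experiment = as.integer(experiment),
                 n_subjects = as.integer(n_subjects),
                 trials_per_subject_per_class =
                   as.integer(trials_per_subject_per_class),
                 k = as.integer(k), train = train, decimate = decimate,
                 analyzers = analyzers, window = window,
                 morf_steps = as.integer(morf_steps),
                 n_explain = as.integer(n_explain),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

experiment_plan <- function(labels, config) {
  switch(config$experiment,
    split_samples_kfold(labels, k = config$k, seed = config$seed),
    split_subjects_kfold(labels, n_test_subjects = 5L, k = config$k,
                         seed = config$seed),
    split_subjects_kfold(labels, n_test_subjects = 10L, k = config$k,
                         seed = config$seed))
}

#' Run a full experiment
#'
#' Generates the synthetic cohort, builds the split plan for the chosen
#' experiment, cross-validates every model, compares models by paired
#' t-tests on per-fold F1, then takes the best network (highest mean F1,
#' ties broken by lower sd; baselines are not eligible for the
#' relevance stage), refits it on the first fold and runs the
#' explanation stage: per-class relevance profiles with marker-level
#' summaries, and an analyzer comparison by MoRF perturbation.  All
#' artifacts (metrics, t-tests, profiles, AOPC tables, the frozen
#' configuration) are written as CSV/JSON under the run directory.
#'
#' @param config an [experiment_config()].
#' @return invisible list with `metrics` (per model), `ttests`,
#'   `best_model`, `explanations` (per class), `analyzer_comparison` and
#'   `out_dir`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$out_dir %||%
    file.path(tempdir(), format(Sys.time(), "gaitxai_run_%Y%m%d_%H%M%S"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg_json <- config
  cfg_json$models <- lapply(config$models, unclass)
  jsonlite::write_json(unclass(cfg_json), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  cohort <- stage("simulate", generate_cohort(
    config$n_subjects, config$trials_per_subject_per_class,
    seed = config$seed))
  plan <- stage("split", experiment_plan(cohort$labels, config))
  write_split_plan(plan, file.path(out_dir, "split_plan.json"))

  results <- list()
  fold_f1 <- list()
  for (nm in names(config$models)) {
    results[[nm]] <- stage(paste0("train:", nm), cross_validate(
      config$models[[nm]], cohort, plan, train_cfg = config$train,
      decimate = config$decimate, seed = derive_seed(config$seed, 301)))
    fold_f1[[nm]] <- results[[nm]]$fold_f1
    utils::write.csv(results[[nm]]$report$folds,
                     file.path(out_dir, sprintf("metrics_%s.csv", nm)),
                     row.names = FALSE)
  }
  summary_df <- do.call(rbind, lapply(names(results), function(nm) {
    s <- results[[nm]]$report$summary
    data.frame(model = nm, metric = s$metric, mean = s$mean, sd = s$sd)
  }))
  utils::write.csv(summary_df, file.path(out_dir, "metrics_summary.csv"),
                   row.names = FALSE)
  ttests <- if (length(fold_f1) >= 2) {
    tt <- stage("ttests", pairwise_model_ttests(fold_f1))
    utils::write.csv(tt, file.path(out_dir, "model_ttests.csv"),
                     row.names = FALSE)
    tt
  } else {
    NULL
  }

  # best network for the explanation stage: highest mean F1, ties by sd
  nn_names <- names(config$models)[vapply(config$models, function(s)
    s$family %in% nn_families, logical(1))]
  explanations <- NULL
  comparison <- NULL
  best <- NULL
  if (length(nn_names)) {
    means <- vapply(nn_names, function(nm) mean(fold_f1[[nm]]), numeric(1))
    sds <- vapply(nn_names, function(nm) stats::sd(fold_f1[[nm]]), numeric(1))
    best <- nn_names[order(-means, sds)][1]
    fold <- plan$folds[[1]]
    std <- standardize_trials(cohort$trials,
                              stats_trials = cohort$trials[fold$train])
    net <- results[[best]]$models[[1]]
    test_trials <- std$trials[fold$test]
    y_test <- cohort$labels$class[fold$test]
    explanations <- stage("explain", {
      lapply(sort(unique(y_test)), function(cl) {
        ex <- tryCatch(
          explain_class(net, test_trials, y_test, cl,
                        decimate = config$decimate),
          error = function(e) NULL)
        if (!is.null(ex)) {
          utils::write.csv(
            data.frame(channel = seq_along(ex$channel_scores),
                       score = ex$channel_scores),
            file.path(out_dir, sprintf("relevance_class%d.csv", cl)),
            row.names = FALSE)
          if (!is.null(ex$markers)) {
            utils::write.csv(ex$markers, file.path(
              out_dir, sprintf("markers_class%d.csv", cl)),
              row.names = FALSE)
          }
        }
        ex
      })
    })
    comparison <- stage("perturb", {
      x_test <- stack_inputs(test_trials, decimate = config$decimate)
      pred <- max.col(predict_proba(net, x_test)) - 1L
      ok <- which(pred == y_test)
      use <- ok[seq_len(min(config$n_explain, length(ok)))]
      samples <- lapply(use, function(i) {
        lapply(x_test, function(a) a[, , i, drop = FALSE])
      })
      cmp <- compare_analyzers(net, samples, y_test[use], config$analyzers,
                               window = config$window, L = config$morf_steps,
                               seed = derive_seed(config$seed, 401))
      utils::write.csv(cmp$aopc, file.path(out_dir, "aopc.csv"),
                       row.names = FALSE)
      utils::write.csv(cmp$curves, file.path(out_dir, "perturbation_curves.csv"),
                       row.names = FALSE)
      cmp
    })
  }
  invisible(list(metrics = lapply(results, `[[`, "report"),
                 fold_f1 = fold_f1, ttests = ttests, best_model = best,
                 explanations = explanations,
                 analyzer_comparison = comparison, out_dir = out_dir))
}
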