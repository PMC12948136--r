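# Plain-text dataset container: one CSV per trial per modality, a labels
# table and a JSON manifest.  CSV values round-trip losslessly (shortest
# representation that re-reads to the same double).

channel_labels <- function(modality) {
  spec <- modality_spec(modality)
  if (modality == "markers") {
    info <- channel_to_marker(seq_len(spec$spatial))
    paste0(info$label, "_", info$coordinate)
  } else {
    sprintf("%s_%02d", modality, seq_len(spec$spatial))
  }
}

#' Write a gait dataset to a directory
#'
#' Lays out `manifest.json`, `labels.csv` (trial_id, subject_id, class,
#' walking speed and per-modality true lengths) and one
#' `<trial_id>_<modality>.csv` matrix per trial and modality, with a
#' header row of channel labels.  Round-trips losslessly through
#' [load_dataset()].
#'
#' @param cohort a `gait_cohort`, or a list with elements `trials`,
#'   `labels` and optionally `manifest`.
#' @param directory output directory (created if missing parent exists).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(cohort, directory) {
  trials <- cohort$trials
  labels <- cohort$labels
  assert_that(length(trials) == nrow(labels),
              "labels table and trial list disagree in length")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = FALSE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create dataset directory '%s'", directory),
                  call. = FALSE)
  }
  lab <- labels
  lab$speed_mps <- vapply(trials, function(tr) tr$speed_mps %||% NA_real_,
                          numeric(1))
  for (m in modality_names()) {
    lab[[paste0("true_length_", m)]] <-
      vapply(trials, function(tr) as.integer(tr$true_length[[m]]), integer(1))
  }
  data.table::fwrite(lab, file.path(directory, "labels.csv"))
  for (i in seq_along(trials)) {
    for (m in modality_names()) {
      x <- data.table::as.data.table(trials[[i]][[m]])
      data.table::setnames(x, channel_labels(m))
      data.table::fwrite(x, file.path(
        directory, sprintf("%s_%s.csv", labels$trial_id[i], m)))
    }
  }
  manifest <- cohort$manifest %||% list()
  manifest$n_trials <- length(trials)
  manifest$modalities <- modality_registry()
  manifest$format <- "csv-v1"
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a gait dataset from a directory
#'
#' Validates every tensor against the modality registry and rebuilds
#' `gait_trial` objects, preserving planted-channel annotations recorded
#' in the manifest.
#'
#' @param directory dataset directory written by [write_dataset()].
#' @return A `gait_cohort`.
#' @export
load_dataset <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  if (!dir.exists(directory)) {
    stop(sprintf("dataset directory '%s' does not exist", directory),
         call. = FALSE)
  }
  if (!file.exists(man_path)) {
    stop(sprintf("no manifest.json in '%s'", directory), call. = FALSE)
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  labels <- as.data.frame(data.table::fread(
    file.path(directory, "labels.csv")))
  assert_that(nrow(labels) > 0, "empty labels table")
  reg <- modality_registry()
  # shapes asserted against the manifest when it narrows them, else registry
  man_mod <- manifest$modalities
  planted <- lapply(manifest$planted_channels, as.integer)
  trials <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    tr <- list()
    for (m in modality_names()) {
      f <- file.path(directory, sprintf("%s_%s.csv", labels$trial_id[i], m))
      if (!file.exists(f)) stop(sprintf("missing matrix file '%s'", f),
                                call. = FALSE)
      x <- as.matrix(data.table::fread(f))
      dimnames(x) <- NULL
      exp_t <- reg$temporal[reg$name == m]
      exp_s <- reg$spatial[reg$name == m]
      if (!is.null(man_mod) && m %in% man_mod$name) {
        exp_t <- man_mod$temporal[man_mod$name == m]
        exp_s <- man_mod$spatial[man_mod$name == m]
      }
      if (nrow(x) != exp_t || ncol(x) != exp_s) {
        stop(sprintf(
          "modality '%s' of trial '%s': expected %d x %d, found %d x %d",
          m, labels$trial_id[i], exp_t, exp_s, nrow(x), ncol(x)),
          call. = FALSE)
      }
      tr[[m]] <- x
    }
    tl <- vapply(modality_names(), function(m) {
      col <- paste0("true_length_", m)
      if (col %in% names(labels)) as.integer(labels[[col]][i]) else nrow(tr[[m]])
    }, integer(1))
    names(tl) <- modality_names()
    tr$speed_class <- as.integer(labels$class[i])
    tr$subject_id <- as.integer(labels$subject_id[i])
    tr$speed_mps <- if ("speed_mps" %in% names(labels)) labels$speed_mps[i] else NA_real_
    tr$true_length <- tl
    tr$planted_channels <- if (length(planted)) planted else NULL
    class(tr) <- "gait_trial"
    trials[[i]] <- tr
  }
  out <- list(trials = trials,
              labels = labels[, c("trial_id", "subject_id", "class")],
              manifest = manifest)
  class(out) <- "gait_cohort"
  out
}
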