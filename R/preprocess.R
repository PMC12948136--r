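# Preprocessing: zero-padding and per-channel standardization with a
# train-only statistics contract (no leakage from validation/test folds).

#' Zero-pad a trial tensor at the tail
#'
#' @param x matrix (frames x channels).
#' @param target_length desired number of frames, `>= nrow(x)`.
#' @return matrix with `target_length` rows; appended rows are exactly zero.
#' @export
zero_pad <- function(x, target_length) {
  assert_that(is.matrix(x), "x must be a frames x channels matrix")
  assert_that(is_count(target_length), "target_length must be a positive integer")
  if (target_length < nrow(x)) {
    stop(sprintf("target_length (%d) is shorter than the input (%d frames)",
                 target_length, nrow(x)), call. = FALSE)
  }
  if (target_length == nrow(x)) return(x)
  rbind(x, matrix(0, target_length - nrow(x), ncol(x)))
}

#' Per-channel standardization statistics
#'
#' Computes channel means and standard deviations over the *unpadded*
#' frames of the supplied training trials, so padding zeros never bias the
#' statistics.  The result is applied to training, validation and test
#' partitions alike via [standardize()], which is the leakage guard: the
#' statistics source must be the training partition only.
#'
#' @param trials list of `gait_trial`s (the training partition).
#' @param modality modality name.
#' @return list with `mean`, `sd` (length = channels) and `modality`.
#' @export
standardization_stats <- function(trials, modality) {
  assert_that(length(trials) > 0, "no trials supplied")
  spec <- modality_spec(modality)
  rows <- lapply(trials, function(tr) {
    n <- tr$true_length[[modality]]
    tr[[modality]][seq_len(n), , drop = FALSE]
  })
  all <- do.call(rbind, rows)
  assert_that(nrow(all) > 0, "zero-length input: no unpadded frames")
  list(mean = colMeans(all), sd = apply(all, 2L, stats::sd),
       modality = modality)
}

#' Standardize a tensor to zero mean and unit variance
#'
#' Applies precomputed per-channel statistics.  Channels whose training
#' standard deviation is (near) zero are mapped to zero through an
#' epsilon guard rather than dividing by zero.
#'
#' @param x matrix (frames x channels).
#' @param stats result of [standardization_stats()], or `NULL` to fit on
#'   `x` itself (population statistics).
#' @param eps guard added to near-zero standard deviations.
#' @return standardized matrix of the same shape.
#' @examples
#' standardize(matrix(c(1, 3), 2, 1))  # -1, 1
#' @export
standardize <- function(x, stats = NULL, eps = 1e-8) {
  assert_that(is.matrix(x) && nrow(x) > 0, "zero-length input")
  if (is.null(stats)) {
    stats <- list(mean = colMeans(x), sd = apply(x, 2L, stats::sd))
  }
  assert_that(length(stats$mean) == ncol(x),
              "statistics do not match the channel count")
  sd <- stats$sd
  centred <- sweep(x, 2L, stats$mean, `-`)
  out <- sweep(centred, 2L, pmax(sd, eps), `/`)
  # constant channels: epsilon guard would otherwise blow up rounding noise
  const <- sd <= eps
  if (any(const)) out[, const] <- 0
  out
}

#' Standardize every trial of a cohort with train-fitted statistics
#'
#' Fits [standardization_stats()] per modality on `stats_trials` (the
#' training partition) and applies them to `trials`.  Only the unpadded
#' frames are transformed; padding zeros stay exactly zero, so the padding
#' never biases channel statistics and remains recognisable downstream.
#'
#' @param trials trials to transform.
#' @param stats_trials trials to fit statistics on (defaults to `trials`).
#' @param modalities which modalities to standardize.
#' @return list with `trials` (transformed) and `stats` (per modality).
#' @export
standardize_trials <- function(trials, stats_trials = trials,
                               modalities = modality_names()) {
  stats <- lapply(modalities, function(m) standardization_stats(stats_trials, m))
  names(stats) <- modalities
  out <- lapply(trials, function(tr) {
    for (m in modalities) {
      n <- tr$true_length[[m]]
      tr[[m]][seq_len(n), ] <- standardize(
        tr[[m]][seq_len(n), , drop = FALSE], stats[[m]])
    }
    tr
  })
  list(trials = out, stats = stats)
}
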