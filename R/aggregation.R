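# Relevance aggregation: turning per-sample relevance maps into ranked,
# smoothed profiles and mapping them onto anatomical markers.

#' Aggregate relevance maps of correctly classified samples
#'
#' Each map is first normalized by its own maximum absolute value (signs
#' are kept), then the element-wise average over samples is taken.  Only
#' maps from samples that the model classified correctly as the class of
#' interest should be supplied; [explain_class()] assembles such a set.
#'
#' @param maps list of `relevance_map`s for one class.
#' @param modality which modality's relevance to aggregate.
#' @return matrix (T x C) raw aggregated profile.
#' @export
aggregate_relevance <- function(maps, modality = "markers") {
  assert_that(length(maps) > 0, "empty set of relevance maps")
  normed <- lapply(maps, function(m) {
    r <- m$relevance[[modality]]
    assert_that(!is.null(r), sprintf("maps carry no '%s' relevance", modality))
    mx <- max(abs(r))
    if (mx == 0) {
      warning("relevance map is identically zero; kept as zeros")
      r
    } else {
      r / mx
    }
  })
  Reduce(`+`, normed) / length(normed)
}

#' Collapse a time-resolved profile to channel-marginal scores
#'
#' Sums absolute relevance over time, yielding one score per channel —
#' the representation used for marker-level summaries.
#'
#' @param profile matrix (T x C).
#' @return numeric vector of length C.
#' @export
channel_marginal <- function(profile) colSums(abs(profile))

smooth_vector <- function(x, passes) {
  n <- length(x)
  if (n < 2L) return(x)
  for (i in seq_len(passes)) {
    left <- c(x[1], x[-n])    # edge weight folded onto the boundary sample
    right <- c(x[-1], x[n])   # so each output's weights still sum to 1
    x <- 0.25 * left + 0.5 * x + 0.25 * right
  }
  x
}

#' Smooth a relevance profile
#'
#' Each pass replaces every value by 50% of itself plus 25% of each
#' neighbour; at the boundaries the out-of-range weight is assigned to
#' the edge sample so the weights still total 1.  Repeated passes
#' (default 3) approximate a Gaussian filter.  Matrices are smoothed
#' along time (rows), per channel.
#'
#' @param profile numeric vector, or matrix (T x C).
#' @param passes number of smoothing passes.
#' @return smoothed profile of the same shape.
#' @examples
#' smooth_profile(c(0, 0, 1, 0, 0), passes = 1)  # 0 .25 .5 .25 0
#' @export
smooth_profile <- function(profile, passes = 3L) {
  assert_that(passes >= 0, "passes must be >= 0")
  if (is.matrix(profile)) {
    apply(profile, 2L, smooth_vector, passes = passes)
  } else {
    smooth_vector(profile, passes)
  }
}

#' Rescale a profile to [0, 1], rank it and select the top variables
#'
#' Min-max rescales the profile, sorts it in descending order (ties
#' broken by ascending variable index) and retains the `k` highest
#' variables.
#'
#' @param profile numeric vector (flattened if time-resolved).
#' @param k number of variables to retain (default 200).
#' @return list with `indices` (top-k variable indices, ranked),
#'   `rescaled` (full profile in [0, 1]) and `k`.
#' @export
rescale_rank_select <- function(profile, k = 200L) {
  profile <- as.vector(profile)
  n <- length(profile)
  if (k > n) {
    warning(sprintf("k = %d exceeds the %d available variables; returning all",
                    k, n))
    k <- n
  }
  rng <- range(profile)
  if (rng[1] == rng[2]) {
    warning("profile is constant; rescaling is undefined, returning zeros")
    rescaled <- rep(0, n)
  } else {
    rescaled <- (profile - rng[1]) / (rng[2] - rng[1])
  }
  ord <- order(-rescaled, seq_len(n))
  list(indices = ord[seq_len(k)], rescaled = rescaled, k = as.integer(k))
}

#' Summarize channel relevance at the marker level
#'
#' Sums marker-channel scores (x, y, z coordinates collapse onto their
#' marker) and returns markers ranked by total relevance.
#'
#' @param scores numeric vector of length 156 (marker-channel scores,
#'   e.g. a channel-marginal profile, possibly zeroed outside a top-k
#'   selection), or a named list/vector of `(index, score)` pairs.
#' @param registry the marker registry.
#' @return data.frame `marker`, `label`, `region`, `side`, `score`,
#'   sorted by decreasing score (ties by marker index).
#' @export
map_to_markers <- function(scores, registry = marker_registry()) {
  assert_that(length(scores) == 156L,
              "scores must cover the 156 marker channels")
  info <- channel_to_marker(seq_len(156L))
  agg <- rowsum(as.numeric(scores), group = info$marker)
  out <- data.frame(marker = as.integer(rownames(agg)),
                    score = as.numeric(agg))
  out <- merge(out, registry, by.x = "marker", by.y = "index", sort = FALSE)
  out <- out[order(-out$score, out$marker),
             c("marker", "label", "region", "side", "score")]
  rownames(out) <- NULL
  out
}

#' Class-wise relevance profile of a trained model
#'
#' Runs the full aggregation protocol for one class: relevance maps are
#' computed for the samples the model classifies correctly as that
#' class, normalized per sample, averaged, smoothed and rescaled.
#'
#' @param net a traced-compatible `gait_network`.
#' @param trials list of standardized trials (e.g. a test partition).
#' @param y integer labels (0-based) for `trials`.
#' @param target_class class to explain.
#' @param modality modality whose relevance is profiled.
#' @param config LRP [rule_config()].
#' @param passes smoothing passes.
#' @param k top-k selection over channel-marginal variables.
#' @param decimate per-modality decimation matching the model's input
#'   shapes (see [stack_inputs()]).
#' @return list with the raw and smoothed time-resolved `profile`,
#'   `channel_scores` (rescaled channel marginals), `selection`
#'   (from [rescale_rank_select()]), `markers` (marker-level summary for
#'   marker channels) and `n_maps`.
#' @export
explain_class <- function(net, trials, y, target_class,
                          modality = "markers", config = rule_config(),
                          passes = 3L, k = 200L, decimate = NULL) {
  x <- stack_inputs(trials, decimate = decimate)
  pred <- max.col(predict_proba(net, x)) - 1L
  keep <- which(pred == y & y == target_class)
  if (!length(keep)) {
    stop(sprintf("no correctly classified samples for class %d", target_class),
         call. = FALSE)
  }
  maps <- lapply(keep, function(i) {
    tr <- forward_trace(net, lapply(x, function(a) a[, , i, drop = FALSE]))
    lrp_backward(tr, target_class, config)
  })
  raw <- aggregate_relevance(maps, modality)
  smoothed <- smooth_profile(raw, passes)
  ch <- channel_marginal(smoothed)
  sel <- rescale_rank_select(ch, k = min(k, length(ch)))
  markers <- if (modality == "markers") {
    map_to_markers(sel$rescaled)
  } else {
    NULL
  }
  list(profile = raw, smoothed = smoothed, channel_scores = sel$rescaled,
       selection = sel, markers = markers, n_maps = length(maps),
       target_class = as.integer(target_class), rule = config$rule)
}
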