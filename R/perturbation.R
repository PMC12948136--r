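# MoRF ("most relevant first") region perturbation and AOPC.
#
# An explanation induces an ordering of input regions; progressively
# replacing the highest-relevance regions with uniform noise and watching
# the class logit f collapse measures how well the explanation found the
# class-critical evidence.  The area over the perturbation curve,
# AOPC = 1/(L+1) * sum_{k=0..L} (f(x_0) - f(x_k)), averaged over samples,
# is the summary score: steeper collapse, larger AOPC, better
# explanation.

#' Tile an input grid and order tiles by relevance
#'
#' Non-overlapping tiles of `window = c(t_span, c_span)` cover the
#' (time x channel) grid; per-tile heat is the sum of relevance inside,
#' and tiles are sorted by decreasing heat (ties by time then channel
#' position).  A time span exceeding the input is an error; a channel
#' span exceeding the channel count is clamped (narrow modalities such
#' as the 8-channel EMG use the full channel width).
#'
#' @param relevance matrix (T x C) of relevance scores.
#' @param window integer `c(t_span, c_span)`, default 7 x 7.
#' @return A `perturbation_order`: data.frame of tiles (`t0`, `t1`,
#'   `c0`, `c1`, `heat`) in perturbation order, with the window and grid
#'   dimensions attached.
#' @export
morf_order <- function(relevance, window = c(7L, 7L)) {
  assert_that(is.matrix(relevance), "relevance must be a T x C matrix")
  ts <- as.integer(window[1]); cs <- as.integer(window[2])
  assert_that(ts >= 1L && cs >= 1L, "window spans must be positive")
  T <- nrow(relevance); C <- ncol(relevance)
  if (ts > T) {
    stop(sprintf("time window (%d) larger than the input (%d frames)",
                 ts, T), call. = FALSE)
  }
  cs <- min(cs, C)
  nt <- ceiling(T / ts); nc <- ceiling(C / cs)
  grid <- expand.grid(ti = seq_len(nt), ci = seq_len(nc))
  t0 <- (grid$ti - 1L) * ts + 1L
  t1 <- pmin(grid$ti * ts, T)
  c0 <- (grid$ci - 1L) * cs + 1L
  c1 <- pmin(grid$ci * cs, C)
  heat <- vapply(seq_len(nrow(grid)), function(i) {
    sum(relevance[t0[i]:t1[i], c0[i]:c1[i]])
  }, numeric(1))
  ord <- order(-heat, t0, c0)
  tiles <- data.frame(t0 = t0, t1 = t1, c0 = c0, c1 = c1, heat = heat)[ord, ]
  rownames(tiles) <- NULL
  structure(list(tiles = tiles, window = c(ts, cs), dim = c(T, C)),
            class = "perturbation_order")
}

#' @export
print.perturbation_order <- function(x, ...) {
  cat(sprintf("<perturbation_order> %d tiles of %d x %d over a %d x %d grid\n",
              nrow(x$tiles), x$window[1], x$window[2], x$dim[1], x$dim[2]))
  invisible(x)
}

channel_ranges <- function(x) {
  list(min = apply(x, 2L, min), max = apply(x, 2L, max))
}

#' Perturb one tile of a sample
#'
#' Replaces the values inside the tile by draws from a uniform
#' distribution over each channel's observed range in the unperturbed
#' sample, so perturbed values stay marginally in-distribution.  Uses the
#' current RNG state; seed the session (or [with_seed()]-style wrappers)
#' for reproducibility.
#'
#' @param x matrix (T x C), possibly already partially perturbed.
#' @param tile one row of a [morf_order()]'s `tiles`.
#' @param bounds per-channel bounds of the *original* sample
#'   (`list(min, max)`); defaults to bounds of `x`.
#' @return perturbed copy of `x`.
#' @export
perturb_step <- function(x, tile, bounds = channel_ranges(x)) {
  rows <- tile$t0:tile$t1
  cols <- tile$c0:tile$c1
  for (cc in cols) {
    x[rows, cc] <- stats::runif(length(rows), bounds$min[cc], bounds$max[cc])
  }
  x
}

#' MoRF perturbation curve and AOPC for one sample
#'
#' Starting from the unperturbed sample (k = 0), applies the
#' perturbation recursion along a tile order for `L` steps, recording
#' the class logit after every step.
#'
#' @param net a `gait_network` (softmax is not applied; f is the class
#'   logit).
#' @param inputs single-sample inputs (named list `modality -> matrix`
#'   or `(T, C, 1)` array).
#' @param modality which modality is perturbed (others are left intact).
#' @param order a [morf_order()].
#' @param L number of perturbation steps; truncated with a warning if it
#'   exceeds the number of tiles.
#' @param target_class class index (0-based) whose logit is tracked;
#'   default: predicted class of the unperturbed sample.
#' @param seed integer seed for the replacement noise.
#' @return A `perturbation_curve`: list with `f` (length L+1), `drops`
#'   (`f[1] - f`), `aopc` and `target_class`.
#' @export
morf_curve <- function(net, inputs, modality, order, L,
                       target_class = NULL, seed = 1L) {
  inputs <- lapply(inputs, function(a) {
    if (length(dim(a)) == 3L) matrix(a, dim(a)[1], dim(a)[2]) else a
  })
  n_tiles <- nrow(order$tiles)
  if (L > n_tiles) {
    warning(sprintf("L = %d exceeds the %d available tiles; truncated",
                    L, n_tiles))
    L <- n_tiles
  }
  to_arrays <- function(lst) lapply(lst, function(m) array(m, c(dim(m), 1L)))
  logit_of <- function(lst) {
    as.vector(network_forward(net, to_arrays(lst), train = FALSE))
  }
  f0 <- logit_of(inputs)
  if (is.null(target_class)) target_class <- which.max(f0) - 1L
  bounds <- channel_ranges(inputs[[modality]])
  f <- numeric(L + 1L)
  pred <- integer(L + 1L)
  f[1] <- f0[target_class + 1L]
  pred[1] <- which.max(f0) - 1L
  x <- inputs
  with_seed(seed, {
    for (k in seq_len(L)) {
      x[[modality]] <- perturb_step(x[[modality]], order$tiles[k, ], bounds)
      fk <- logit_of(x)
      f[k + 1L] <- fk[target_class + 1L]
      pred[k + 1L] <- which.max(fk) - 1L
    }
  })
  drops <- f[1] - f
  structure(list(f = f, drops = drops, pred = pred,
                 aopc = sum(drops) / (L + 1L),
                 L = as.integer(L), target_class = as.integer(target_class),
                 modality = modality),
            class = "perturbation_curve")
}

#' @export
print.perturbation_curve <- function(x, ...) {
  cat(sprintf("<perturbation_curve> class %d, %d steps, AOPC %.4f\n",
              x$target_class, x$L, x$aopc))
  invisible(x)
}

#' Area over the perturbation curve
#'
#' @param curve a `perturbation_curve`.
#' @return the AOPC scalar.
#' @export
aopc <- function(curve) curve$aopc

#' Compare explanation analyzers by perturbation
#'
#' For every analyzer and sample, derives a tile ordering from the
#' analyzer's relevance map, runs the MoRF recursion with a shared
#' replacement-noise stream (so comparisons are paired across
#' analyzers), and aggregates AOPC and accuracy-decay curves.  The
#' analyzer name `"random"` is reserved for a random tile ordering
#' baseline.  `direction = "keep_top"` instead removes the *least*
#' relevant tiles first, tracking how performance persists while the
#' most relevant features are kept.
#'
#' @param net a `gait_network`.
#' @param samples list of single-sample input lists.
#' @param y integer labels (0-based), one per sample; used as the target
#'   class and for the accuracy curves.
#' @param analyzers named list: each element is either a function
#'   `(net, inputs, target_class) -> relevance_map` or one of the strings
#'   `"lrp_epsilon"`, `"lrp_z"`, `"lrp_alpha_beta"`, `"lrp_flat"`,
#'   `"lrp_preset_a_flat"`, `"gradient"`, `"input"`, `"guided_backprop"`,
#'   `"deconvnet"`, `"random"`.
#' @param modality modality to perturb.
#' @param window tile window, see [morf_order()].
#' @param L perturbation steps.
#' @param seed base seed for replacement noise (and random orderings).
#' @param direction `"morf"` or `"keep_top"`.
#' @return list with `aopc` (data.frame analyzer/mean AOPC/n),
#'   `per_sample` (matrix analyzers x samples), `curves` (long
#'   data.frame analyzer/step/mean logit drop/accuracy).
#' @export
compare_analyzers <- function(net, samples, y, analyzers,
                              modality = "markers", window = c(7L, 7L),
                              L = 20L, seed = 1L,
                              direction = c("morf", "keep_top")) {
  direction <- match.arg(direction)
  assert_that(length(analyzers) >= 2, "need at least two analyzers")
  assert_that(length(samples) == length(y), "labels do not match samples")
  nm <- names(analyzers)
  assert_that(!is.null(nm) && all(nzchar(nm)), "analyzers must be named")
  relevance_for <- function(a, inputs, cls) {
    if (is.function(a)) return(a(net, inputs, cls))
    switch(a,
      random = NULL,
      gradient = , input = , guided_backprop = , deconvnet =
        baseline_analyzer(net, inputs, a, target_class = cls),
      lrp_epsilon = , lrp_z = , lrp_alpha_beta = , lrp_flat = ,
      lrp_preset_a_flat = {
        rule <- sub("^lrp_", "", a)
        lrp_backward(forward_trace(net, inputs), cls, rule_config(rule))
      },
      stop(sprintf("unknown analyzer '%s'", a), call. = FALSE))
  }
  n_s <- length(samples)
  per_sample <- matrix(NA_real_, length(analyzers), n_s,
                       dimnames = list(nm, NULL))
  drops_acc <- array(NA_real_, c(length(analyzers), n_s, L + 1L))
  correct <- array(NA_real_, c(length(analyzers), n_s, L + 1L))
  for (si in seq_len(n_s)) {
    inputs <- samples[[si]]
    cls <- y[si]
    for (ai in seq_along(analyzers)) {
      res <- tryCatch({
        a <- analyzers[[ai]]
        rmap <- relevance_for(a, inputs, cls)
        xm <- inputs[[modality]]
        if (length(dim(xm)) == 3L) xm <- matrix(xm, dim(xm)[1], dim(xm)[2])
        ord <- if (is.null(rmap)) {
          o <- morf_order(matrix(0, nrow(xm), ncol(xm)), window)
          o$tiles <- o$tiles[with_seed(derive_seed(seed, 51, si),
                                       sample(nrow(o$tiles))), ]
          o
        } else {
          morf_order(rmap$relevance[[modality]], window)
        }
        if (direction == "keep_top") {
          ord$tiles <- ord$tiles[rev(seq_len(nrow(ord$tiles))), ]
        }
        morf_curve(net, inputs, modality, ord, L, target_class = cls,
                   seed = derive_seed(seed, 73, si))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("analyzer '%s' failed on sample %d: %s",
                        nm[ai], si, conditionMessage(res)))
        next
      }
      per_sample[ai, si] <- res$aopc
      drops_acc[ai, si, ] <- res$drops
      correct[ai, si, ] <- as.numeric(res$pred == cls)
    }
  }
  agg <- data.frame(
    analyzer = nm,
    mean_aopc = rowMeans(per_sample, na.rm = TRUE),
    n = rowSums(!is.na(per_sample)))
  curves <- do.call(rbind, lapply(seq_along(nm), function(ai) {
    data.frame(analyzer = nm[ai], step = 0:L,
               mean_drop = apply(drops_acc[ai, , , drop = FALSE], 3L, mean,
                                 na.rm = TRUE),
               accuracy = apply(correct[ai, , , drop = FALSE], 3L, mean,
                                na.rm = TRUE))
  }))
  list(aopc = agg, per_sample = per_sample, curves = curves)
}

#' @export
plot.perturbation_curve <- function(x, ...) {
  graphics::plot(0:x$L, x$f, type = "b", pch = 16,
                 xlab = "perturbation step k",
                 ylab = sprintf("class-%d logit", x$target_class), ...)
  graphics::abline(h = x$f[1], lty = 3)
  invisible(x)
}
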