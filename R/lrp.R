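# Layer-wise relevance propagation.
#
# The class-c logit (softmax removed) is redistributed backwards through
# the traced network under a conservation principle: at every layer the
# incoming relevance is split over the layer's inputs in proportion to
# their contribution to each pre-activation z_k = sum_j a_j w_jk + b_k.
# Rules differ in how the contribution ratio a_j w_jk / z_k is stabilized
# (epsilon rule), split into excitatory/inhibitory parts (alpha-beta
# rule) or flattened (flat rule).  Bias terms absorb their own share, so
# strict conservation holds for bias-free networks.

#' Relevance-propagation rule configuration
#'
#' @param rule `"epsilon"`, `"z"` (epsilon = 0), `"alpha_beta"`, `"flat"`
#'   or `"preset_a_flat"` (composite: epsilon on dense layers, alpha=1 /
#'   beta=0 on convolution layers, flat on the input layer).
#' @param epsilon non-negative stabilizer added to the denominators.
#' @param alpha,beta positive/negative contribution weights; conservation
#'   requires `alpha - beta = 1` (default alpha 2, beta 1).
#' @return A `rule_config`.
#' @export
rule_config <- function(rule = c("epsilon", "z", "alpha_beta", "flat",
                                 "preset_a_flat"),
                        epsilon = 1e-7, alpha = 2, beta = 1) {
  rule <- match.arg(rule)
  assert_that(epsilon >= 0, "epsilon must be >= 0")
  assert_that(alpha >= 1, "alpha must be >= 1")
  assert_that(isTRUE(all.equal(alpha - beta, 1)),
              "alpha - beta must equal 1 for conservation")
  structure(list(rule = rule, epsilon = epsilon, alpha = alpha, beta = beta),
            class = "rule_config")
}

traceable_types <- c("conv1d", "dense", "relu", "dropout", "pool", "adapool",
                     "gap", "flatten", "lstm")

#' Record a forward trace of a model on one sample
#'
#' Runs the network in inference mode on a single trial and snapshots,
#' for every layer, its inputs, pre-activations, weights and pooling
#' switches — everything relevance propagation needs.  Supported
#' families are the CNN/MLP stacks and the TCN (and the CNN+LSTM up to
#' its recurrent readout); attention and bidirectional-GRU models cannot
#' be traced.
#'
#' @param net a `gait_network`.
#' @param inputs named list `modality -> matrix(T, C)` or
#'   `array(T, C, 1)` for one sample.
#' @return A `layer_trace` with elements `logits`, `streams`, `head`,
#'   `widths` and `inputs`.
#' @export
forward_trace <- function(net, inputs) {
  all_layers <- c(unlist(lapply(net$streams, `[[`, "layers")), net$head)
  bad <- setdiff(vapply(all_layers, `[[`, "", "type"), traceable_types)
  if (length(bad)) {
    stop(sprintf(
      "unsupported architecture for relevance tracing: layer type(s) %s",
      paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  inputs <- lapply(inputs, function(x) {
    if (length(dim(x)) == 3L) {
      assert_that(dim(x)[3] == 1L, "forward_trace takes a single sample")
      array(x, dim(x))
    } else {
      array(x, c(dim(x), 1L))
    }
  })
  logits <- network_forward(net, inputs, train = FALSE)
  snap_layer <- function(ly) {
    list(type = ly$type, config = ly$config,
         W = if (!is.null(ly$params$W)) ly$params$W$W else NULL,
         b = if (!is.null(ly$params$b)) ly$params$b$W else NULL,
         cache = as.list(ly$cache))
  }
  streams <- lapply(net$streams, function(s) {
    list(modality = s$modality, layers = lapply(s$layers, snap_layer))
  })
  head <- lapply(net$head, snap_layer)
  structure(list(net = net, inputs = inputs, logits = as.vector(logits),
                 streams = streams, head = head,
                 merge = net$merge, widths = net$.widths,
                 n_classes = net$n_classes),
            class = "layer_trace")
}

#' Replay a trace through the live network
#'
#' @param trace a `layer_trace`.
#' @return the logit vector recomputed from the stored inputs.
#' @export
replay_trace <- function(trace) {
  as.vector(network_forward(trace$net, trace$inputs, train = FALSE))
}

# relevance through one linear map: X (rows x J), W (J x K), Z (rows x K),
# R (rows x K) -> contributions (rows x J)
lin_relevance <- function(X, W, Z, R, rule, eps, alpha, beta) {
  if (rule == "flat") {
    return(matrix(rowSums(R) / ncol(X), nrow(X), ncol(X)))
  }
  if (rule == "alpha_beta") {
    Xp <- pmax(X, 0); Xn <- pmin(X, 0)
    Wp <- pmax(W, 0); Wn <- pmin(W, 0)
    Zp <- Xp %*% Wp + Xn %*% Wn
    Zn <- Xp %*% Wn + Xn %*% Wp
    Sp <- ifelse(Zp > 0, R / (Zp + eps), 0) * alpha
    Sn <- if (beta != 0) ifelse(Zn < 0, -R / (Zn - eps), 0) * beta else NULL
    out <- (Sp %*% t(Wp)) * Xp + (Sp %*% t(Wn)) * Xn
    if (!is.null(Sn)) {
      out <- out + (Sn %*% t(Wn)) * Xp + (Sn %*% t(Wp)) * Xn
    }
    return(out)
  }
  # epsilon rule; z rule is epsilon = 0 with a zero-denominator guard
  Zs <- ifelse(Z >= 0, Z + eps, Z - eps)
  S <- ifelse(Zs != 0, R / Zs, 0)
  (S %*% t(W)) * X
}

layer_relevance <- function(snap, R, cfg_rule, first_parametric) {
  rule <- cfg_rule$rule
  eps <- cfg_rule$epsilon
  alpha <- cfg_rule$alpha; beta <- cfg_rule$beta
  if (rule == "z") eps <- 0
  if (rule == "preset_a_flat") {
    # composite: flat at the input layer, alpha1-beta0 on conv, epsilon on
    # dense layers
    if (first_parametric) {
      rule <- "flat"
    } else if (snap$type == "conv1d") {
      rule <- "alpha_beta"; alpha <- 1; beta <- 0
    } else {
      rule <- "epsilon"
    }
  }
  cc <- snap$cache
  switch(snap$type,
    conv1d = {
      g <- if (is.list(R)) R$x else R
      contrib <- lin_relevance(cc$col, snap$W, cc$z, g, rule, eps, alpha, beta)
      dx <- conv_col2im(contrib, cc$T_in, cc$N, snap$config$in_ch,
                        snap$config, cc$geo, cc$idx)
      rm_batch(dx, cc$T_in, cc$N)
    },
    dense = lin_relevance(cc$x, snap$W, cc$z, R, rule, eps, alpha, beta),
    relu = R,
    dropout = R,
    pool = {
      p <- snap$config$size
      g <- R$x
      if (snap$config$mode == "avg") {
        # uniform redistribution inside each window
        dbk <- matrix(rep(as.vector(g) / p, each = p),
                      cc$T_out * p * cc$N, cc$C)
      } else {
        # winner-take-all: relevance follows the recorded argmax switch
        dbk <- matrix(0, cc$T_out * p * cc$N, cc$C)
        for (j in seq_len(p)) {
          sel <- cc$amax == j
          tmp <- matrix(0, cc$T_out * cc$N, cc$C)
          tmp[sel] <- g[sel]
          dbk[seq(j, nrow(dbk), by = p), ] <- tmp
        }
      }
      dx <- matrix(0, cc$T_in * cc$N, cc$C)
      dx[cc$keep, ] <- dbk
      rm_batch(dx, cc$T_in, cc$N)
    },
    adapool = {
      L <- snap$config$out_len
      idx <- rep(cc$bin, cc$N) + rep((0:(cc$N - 1L)) * L, each = cc$T_in)
      dx <- R$x[idx, , drop = FALSE] / cc$counts[rep(cc$bin, cc$N)]
      rm_batch(dx, cc$T_in, cc$N)
    },
    gap = {
      # redistribute proportionally to the (non-negative, post-ReLU)
      # activations that were averaged
      x <- cc$x
      denom <- colSums(x)
      denom <- ifelse(denom >= 0, denom + eps, denom - eps)
      share <- sweep(x, 2L, ifelse(denom != 0, denom, Inf), `/`)
      dx <- share * matrix(R, cc$T_in * cc$N, ncol(x), byrow = TRUE)
      rm_batch(dx, cc$T_in, cc$N)
    },
    flatten = {
      A <- array(R, c(cc$N, cc$T_in, cc$C))
      rm_batch(matrix(aperm(A, c(2L, 1L, 3L)), cc$T_in * cc$N, cc$C),
               cc$T_in, cc$N)
    },
    lstm = stop(
      "relevance propagation through recurrent gates is not supported",
      call. = FALSE),
    stop(sprintf("no relevance rule for layer type '%s'", snap$type),
         call. = FALSE)
  )
}

#' Layer-wise relevance propagation over a forward trace
#'
#' Initializes relevance as the class-`target_class` logit (all other
#' classes excluded) and redistributes it backwards layer by layer to the
#' inputs.
#'
#' @param trace a [forward_trace()].
#' @param target_class class index (0-based) whose logit is decomposed.
#' @param config a [rule_config()].
#' @return A `relevance_map`: list with `relevance` (named list
#'   `modality -> matrix(T, C)`), `target_class`, `rule`, `logit` and the
#'   realized relevance sum `total`.
#' @export
lrp_backward <- function(trace, target_class, config = rule_config()) {
  assert_that(target_class %in% 0:(trace$n_classes - 1L),
              "target_class out of range")
  R <- matrix(0, 1L, trace$n_classes)
  R[1L, target_class + 1L] <- trace$logits[target_class + 1L]
  if (all(trace$logits == 0)) {
    warning("dead network: all logits are zero; returning a zero map")
  }
  for (j in rev(seq_along(trace$head))) {
    R <- layer_relevance(trace$head[[j]], R, config, first_parametric = FALSE)
  }
  n_streams <- length(trace$streams)
  stream_R <- vector("list", n_streams)
  if (trace$merge == "vector_concat") {
    off <- 0L
    for (i in seq_len(n_streams)) {
      w <- trace$widths[i]
      stream_R[[i]] <- R[, (off + 1L):(off + w), drop = FALSE]
      off <- off + w
    }
  } else if (trace$merge == "seq_concat") {
    off <- 0L
    for (i in seq_len(n_streams)) {
      w <- trace$widths[i]
      stream_R[[i]] <- rm_batch(R$x[, (off + 1L):(off + w), drop = FALSE],
                                R$T, R$N)
      off <- off + w
    }
  } else {
    stream_R[[1]] <- R
  }
  relevance <- list()
  for (i in seq_len(n_streams)) {
    layers <- trace$streams[[i]]$layers
    first_idx <- which(vapply(layers, function(l) l$type %in%
                                c("conv1d", "dense"), logical(1)))[1]
    Rs <- stream_R[[i]]
    for (j in rev(seq_along(layers))) {
      Rs <- layer_relevance(layers[[j]], Rs, config,
                            first_parametric = identical(j, first_idx))
    }
    m <- trace$streams[[i]]$modality
    mat <- if (is.list(Rs)) matrix(Rs$x, Rs$T, ncol(Rs$x)) else Rs
    if (is.null(relevance[[m]])) {
      relevance[[m]] <- mat
    } else {
      relevance[[m]] <- relevance[[m]] + mat
    }
  }
  bad <- !vapply(relevance, function(r) all(is.finite(r)), logical(1))
  if (any(bad)) {
    warning("non-finite relevance entries clipped to zero")
    relevance[bad] <- lapply(relevance[bad], function(r) {
      r[!is.finite(r)] <- 0
      r
    })
  }
  structure(list(relevance = relevance,
                 target_class = as.integer(target_class),
                 rule = config$rule,
                 logit = trace$logits[target_class + 1L],
                 total = sum(vapply(relevance, sum, numeric(1)))),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf(
    "<relevance_map> rule '%s', class %d, f_c = %.4f, sum(R) = %.4f\n",
    x$rule, x$target_class, x$logit, x$total))
  invisible(x)
}

#' Gradient-family saliency baselines
#'
#' Reference analyzers to compare LRP against: the raw input, the
#' gradient of the class logit, guided backpropagation (negative
#' gradients zeroed where the forward ReLU was inactive or the gradient
#' negative) and deconvnet (negative gradients zeroed regardless of the
#' forward sign).
#'
#' @param net a `gait_network` (any differentiable family).
#' @param inputs single-sample inputs as in [forward_trace()].
#' @param method `"gradient"`, `"input"`, `"guided_backprop"` or
#'   `"deconvnet"`.
#' @param target_class class index (0-based); default: predicted class.
#' @return A `relevance_map`.
#' @export
baseline_analyzer <- function(net, inputs,
                              method = c("gradient", "input",
                                         "guided_backprop", "deconvnet"),
                              target_class = NULL) {
  method <- match.arg(method)
  inputs <- lapply(inputs, function(x) {
    if (length(dim(x)) == 3L) x else array(x, c(dim(x), 1L))
  })
  logits <- network_forward(net, inputs, train = FALSE)
  if (is.null(target_class)) target_class <- which.max(logits) - 1L
  if (method == "input") {
    rel <- lapply(inputs, function(x) matrix(x, dim(x)[1], dim(x)[2]))
  } else {
    mode <- switch(method, gradient = "standard",
                   guided_backprop = "guided", deconvnet = "deconv")
    dlogits <- matrix(0, 1L, net$n_classes)
    dlogits[1L, target_class + 1L] <- 1
    g <- network_backward(net, dlogits, relu_mode = mode)
    rel <- list()
    for (i in seq_along(g)) {
      m <- names(g)[i]
      mat <- matrix(g[[i]], dim(g[[i]])[1], dim(g[[i]])[2])
      rel[[m]] <- if (is.null(rel[[m]])) mat else rel[[m]] + mat
    }
  }
  structure(list(relevance = rel, target_class = as.integer(target_class),
                 rule = method, logit = logits[target_class + 1L],
                 total = sum(vapply(rel, sum, numeric(1)))),
            class = "relevance_map")
}
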