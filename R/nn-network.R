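# Network container: per-modality streams, a feature-fusion merge and a
# classification head; Adam training with validation-based early stopping.

new_network <- function(streams, head, merge = "vector_concat",
                        family = "custom", n_classes = 4L, spec = NULL) {
  net <- new.env(parent = emptyenv())
  net$streams <- streams      # list of list(modality=, layers=list(...))
  net$head <- head            # list of layers
  net$merge <- merge          # "vector_concat", "seq_concat" or "none"
  net$family <- family
  net$n_classes <- n_classes
  net$spec <- spec
  class(net) <- "gait_network"
  net
}

#' @export
print.gait_network <- function(x, ...) {
  cat(sprintf("<gait_network> family '%s', %d stream(s) [%s], %d classes\n",
              x$family, length(x$streams),
              paste(vapply(x$streams, `[[`, "", "modality"), collapse = ", "),
              x$n_classes))
  invisible(x)
}

network_params <- function(net) {
  out <- list()
  seen <- integer(0)
  add <- function(layers) {
    for (ly in layers) {
      for (p in layer_params(ly)) {
        if (!(p$id %in% seen)) {
          seen <<- c(seen, p$id)
          out[[length(out) + 1L]] <<- p
        }
      }
    }
  }
  for (s in net$streams) add(s$layers)
  add(net$head)
  out
}

# inputs: named list modality -> array (T, C, N); streams index into it
network_forward <- function(net, inputs, train = FALSE) {
  outs <- vector("list", length(net$streams))
  for (i in seq_along(net$streams)) {
    s <- net$streams[[i]]
    x <- inputs[[s$modality]]
    assert_that(!is.null(x), sprintf("missing input for modality '%s'",
                                     s$modality))
    cur <- if (is.list(x)) x else rm_from_array(x)  # rm batch fast path
    for (ly in s$layers) cur <- layer_forward(ly, cur, train)
    outs[[i]] <- cur
  }
  merged <- if (net$merge == "vector_concat") {
    net$.widths <- vapply(outs, ncol, integer(1))
    do.call(cbind, outs)
  } else if (net$merge == "seq_concat") {
    Ts <- vapply(outs, `[[`, integer(1), "T")
    assert_that(length(unique(Ts)) == 1L,
                "seq_concat requires equal stream sequence lengths")
    net$.widths <- vapply(outs, function(o) ncol(o$x), integer(1))
    rm_batch(do.call(cbind, lapply(outs, `[[`, "x")), Ts[1], outs[[1]]$N)
  } else {
    outs[[1]]
  }
  cur <- merged
  for (ly in net$head) cur <- layer_forward(ly, cur, train)
  cur
}

# returns per-stream input gradients as arrays (T, C, N)
network_backward <- function(net, dlogits, relu_mode = "standard") {
  cur <- dlogits
  for (ly in rev(net$head)) cur <- layer_backward(ly, cur, relu_mode)
  grads <- vector("list", length(net$streams))
  if (net$merge == "vector_concat") {
    off <- 0L
    for (i in seq_along(net$streams)) {
      w <- net$.widths[i]
      grads[[i]] <- cur[, (off + 1L):(off + w), drop = FALSE]
      off <- off + w
    }
  } else if (net$merge == "seq_concat") {
    off <- 0L
    for (i in seq_along(net$streams)) {
      w <- net$.widths[i]
      grads[[i]] <- rm_batch(cur$x[, (off + 1L):(off + w), drop = FALSE],
                             cur$T, cur$N)
      off <- off + w
    }
  } else {
    grads[[1]] <- cur
  }
  out <- vector("list", length(net$streams))
  for (i in seq_along(net$streams)) {
    g <- grads[[i]]
    for (ly in rev(net$streams[[i]]$layers)) g <- layer_backward(ly, g, relu_mode)
    out[[i]] <- rm_to_array(g)
  }
  names(out) <- vapply(net$streams, `[[`, "", "modality")
  out
}

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class probabilities for a batch of inputs
#'
#' Runs the network in inference mode and applies the softmax head.
#'
#' @param net a `gait_network`.
#' @param inputs named list `modality -> array(T, C, N)`; see
#'   [stack_inputs()].
#' @return matrix (N x n_classes) of probabilities, rows summing to 1.
#' @export
predict_proba <- function(net, inputs) {
  check_input_shapes(net, inputs)
  p <- softmax(network_forward(net, inputs, train = FALSE))
  dimnames(p) <- NULL
  p
}

check_input_shapes <- function(net, inputs) {
  for (s in net$streams) {
    x <- inputs[[s$modality]]
    assert_that(!is.null(x) && length(dim(x)) == 3L,
                sprintf("input for modality '%s' must be a (T, C, N) array",
                        s$modality))
    if (!is.null(s$in_shape)) {
      assert_that(all(dim(x)[1:2] == s$in_shape), sprintf(
        "modality '%s': expected %d x %d input, got %d x %d",
        s$modality, s$in_shape[1], s$in_shape[2], dim(x)[1], dim(x)[2]))
    }
  }
  invisible(TRUE)
}

# --- training ---------------------------------------------------------------

#' Training configuration
#'
#' Adam optimizer with categorical cross-entropy loss; training stops
#' early after `patience` epochs without validation-loss improvement and
#' the best weights are restored.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap (must be <= 1000).
#' @param patience early-stopping patience in epochs.
#' @param seed seed for shuffling, dropout and (re)initialisation order.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32L,
                         max_epochs = 200L, patience = 20L, seed = 1L) {
  assert_that(max_epochs <= 1000L, "max_epochs must be <= 1000")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$m)) {
      p$m <- p$g * 0
      p$v <- p$g * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$g
    p$v <- beta2 * p$v + (1 - beta2) * p$g^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$W <- p$W - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

slice_inputs <- function(inputs, idx) {
  lapply(inputs, function(a) a[, , idx, drop = FALSE])
}

# pre-transposed (T, N, C) layout: batch slicing without a per-batch aperm
prepare_tnc <- function(inputs) lapply(inputs, aperm, c(1L, 3L, 2L))
rm_slice_tnc <- function(a, idx) {
  d <- dim(a)
  rm_batch(matrix(a[, idx, , drop = FALSE], d[1] * length(idx), d[3]),
           d[1], length(idx))
}

one_hot <- function(y, n_classes) {
  m <- matrix(0, length(y), n_classes)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

eval_loss_acc <- function(net, tnc, y, batch_size = 64L) {
  n <- dim(tnc[[1]])[2]
  loss <- 0; correct <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    p <- softmax(network_forward(net, lapply(tnc, rm_slice_tnc, idx),
                                 train = FALSE))
    loss <- loss - sum(log(pmax(p[cbind(seq_along(idx), y[idx] + 1L)], 1e-12)))
    correct <- correct + sum(max.col(p) - 1L == y[idx])
  }
  c(loss = loss / n, acc = correct / n)
}

snapshot_params <- function(params) lapply(params, function(p) p$W)
restore_params <- function(params, snap) {
  for (i in seq_along(params)) params[[i]]$W <- snap[[i]]
  invisible(NULL)
}

#' Train a network with Adam and early stopping
#'
#' @param net a `gait_network` built by [build_model()].
#' @param inputs named list `modality -> array(T, C, N)` of standardized
#'   training tensors (see [stack_inputs()]).
#' @param y integer class labels in `0..n_classes-1`.
#' @param val_inputs,val_y validation partition used for early stopping;
#'   if `NULL`, no early stopping is applied and training runs to
#'   `max_epochs`.
#' @param config a [train_config()].
#' @return `net`, invisibly, with a `history` data.frame attached
#'   (`net$history`): per-epoch train/validation loss and accuracy.
#' @export
train_network <- function(net, inputs, y, val_inputs = NULL, val_y = NULL,
                          config = train_config()) {
  n <- dim(inputs[[1]])[3]
  assert_that(n > 0 && length(y) == n, "empty or mismatched training data")
  has_val <- !is.null(val_inputs) && !is.null(val_y) &&
    length(val_y) > 0
  params <- network_params(net)
  tnc <- prepare_tnc(inputs)
  val_tnc <- if (has_val) prepare_tnc(val_inputs) else NULL
  best_loss <- Inf
  best_snap <- snapshot_params(params)
  wait <- 0L
  hist <- vector("list", config$max_epochs)
  step_t <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- lapply(tnc, rm_slice_tnc, idx)
        yb <- y[idx]
        zero_grads(params)
        logits <- network_forward(net, xb, train = TRUE)
        p <- softmax(logits)
        if (any(!is.finite(p))) {
          stop("training diverged: non-finite loss", call. = FALSE)
        }
        ep_loss <- ep_loss -
          sum(log(pmax(p[cbind(seq_along(idx), yb + 1L)], 1e-12)))
        ep_correct <- ep_correct + sum(max.col(p) - 1L == yb)
        dlogits <- (p - one_hot(yb, net$n_classes)) / length(idx)
        network_backward(net, dlogits)
        step_t <- step_t + 1L
        adam_step(params, config$learning_rate, step_t)
      }
      row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                        train_acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (has_val) {
        va <- eval_loss_acc(net, val_tnc, val_y)
        row$val_loss <- va[["loss"]]; row$val_acc <- va[["acc"]]
        if (va[["loss"]] < best_loss - 1e-8) {
          best_loss <- va[["loss"]]
          best_snap <- snapshot_params(params)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist[[epoch]] <- row
      if (has_val && wait >= config$patience) break
    }
  })
  if (has_val) restore_params(params, best_snap)
  net$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  invisible(net)
}

#' Stack trial tensors into per-modality batch arrays
#'
#' Optionally block-averages the time axis by a per-modality `decimate`
#' factor while stacking, the standard way to scale the high-rate
#' modalities down to a tractable sequence length.  A model consuming
#' decimated inputs must be built with matching `shapes` (see
#' [decimated_shapes()]).
#'
#' @param trials list of (standardized) `gait_trial`s.
#' @param modalities modalities to stack.
#' @param decimate named integer vector of temporal block-average
#'   factors (default: no decimation).
#' @return named list `modality -> array(T, C, N)`.
#' @export
stack_inputs <- function(trials, modalities = modality_names(),
                         decimate = NULL) {
  out <- lapply(modalities, function(m) {
    d <- as.integer(decimate[m] %||% 1L)
    if (is.na(d)) d <- 1L
    x1 <- decimate_matrix(trials[[1]][[m]], d)
    a <- array(0, c(nrow(x1), ncol(x1), length(trials)))
    a[, , 1] <- x1
    if (length(trials) > 1L) {
      for (i in 2:length(trials)) {
        a[, , i] <- decimate_matrix(trials[[i]][[m]], d)
      }
    }
    a
  })
  names(out) <- modalities
  out
}

decimate_matrix <- function(x, d) {
  if (d <= 1L) return(x)
  T2 <- nrow(x) %/% d
  x <- x[seq_len(T2 * d), , drop = FALSE]
  matrix(colMeans(matrix(x, d, T2 * ncol(x))), T2, ncol(x))
}

#' Input shapes after temporal decimation
#'
#' @param decimate named integer vector of per-modality factors.
#' @return named list `modality -> c(T, C)` suitable for the `shapes`
#'   hyperparameter of [build_model()].
#' @export
decimated_shapes <- function(decimate = NULL) {
  reg <- modality_registry()
  out <- lapply(seq_len(nrow(reg)), function(i) {
    d <- as.integer(decimate[reg$name[i]] %||% 1L)
    if (is.na(d)) d <- 1L
    c(reg$temporal[i] %/% d, reg$spatial[i])
  })
  names(out) <- reg$name
  out
}
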