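# Model zoo: multi-stream CNN families, hybrid CNN+LSTM, TCN, bidirectional
# GRU, Transformer encoder, and the classical LDA/QDA/SVM baselines.

nn_families <- c("single_cnn", "dual_cnn", "quads_cnn", "fusion_cnn",
                 "cnn_lstm", "tcn", "gru", "transformer")
baseline_families <- c("lda", "qda", "svm")

#' Model specification
#'
#' @param family one of `single_cnn`, `dual_cnn`, `quads_cnn`,
#'   `fusion_cnn`, `cnn_lstm`, `tcn`, `gru`, `transformer`, `lda`, `qda`,
#'   `svm`.  The multi-stream CNN families take 1/2/4/4 modalities; the
#'   hybrid CNN+LSTM fuses all four; the sequence models and the
#'   classical baselines operate on a single modality.
#' @param modalities character vector of modality names.
#' @param hyper named list of hyperparameters overriding the defaults
#'   (see [build_model()]).
#' @return A `model_spec`.
#' @export
model_spec <- function(family, modalities, hyper = list()) {
  family <- match.arg(family, c(nn_families, baseline_families))
  modalities <- as.character(modalities)
  assert_that(all(modalities %in% modality_names()),
              "unknown modality name(s)")
  n <- length(modalities)
  need <- switch(family,
    single_cnn = 1L, dual_cnn = 2L, quads_cnn = 4L, fusion_cnn = 4L,
    cnn_lstm = 4L, tcn = 1L, gru = 1L, transformer = 1L,
    lda = 1L, qda = 1L, svm = 1L)
  if (n != need) {
    stop(sprintf("family '%s' takes exactly %d modalit%s (got %d)",
                 family, need, if (need == 1L) "y" else "ies", n),
         call. = FALSE)
  }
  structure(list(family = family, modalities = modalities, hyper = hyper),
            class = "model_spec")
}

default_hyper <- function(family) {
  base <- list(
    filters = c(32L, 64L, 96L), kernel = 7L, stride = 2L,
    dropout = 0.3, embed = 128L, head = 128L,
    bias = TRUE, shapes = NULL
  )
  extra <- switch(family,
    fusion_cnn = list(head = c(256L, 128L)),
    cnn_lstm = list(seq_len = 32L, lstm_hidden = 128L),
    tcn = list(filters = c(12L, 24L, 48L, 96L), kernel = 5L,
               dilations = c(1L, 2L, 4L, 8L), dense = 100L),
    gru = list(gru_units = c(128L, 256L, 256L),
               head = c(512L, 256L, 128L)),
    transformer = list(d_model = 64L, n_heads = 4L, d_ff = 128L,
                       n_blocks = 2L),
    list())
  utils::modifyList(base, extra)
}

input_shape <- function(modality, hyper) {
  if (!is.null(hyper$shapes) && modality %in% names(hyper$shapes)) {
    as.integer(hyper$shapes[[modality]])
  } else {
    spec <- modality_spec(modality)
    c(spec$temporal, spec$spatial)
  }
}

# convolutional encoder for one stream; returns list(layers, out_T, out_ch)
build_conv_stream <- function(modality, hyper, with_gap = TRUE,
                              share = NULL) {
  sh <- input_shape(modality, hyper)
  T <- sh[1]; C <- sh[2]
  layers <- list()
  in_ch <- C
  si <- 1L
  for (f in hyper$filters) {
    shared <- if (!is.null(share)) share$layers[[length(layers) + 1L]] else NULL
    conv <- ly_conv1d(in_ch, f, hyper$kernel, stride = hyper$stride,
                      bias = hyper$bias, share = shared)
    layers <- c(layers, list(conv, ly_relu()))
    if (hyper$dropout > 0) layers <- c(layers, list(ly_dropout(hyper$dropout)))
    geo <- conv_geometry(conv$config, T)
    T <- geo$T_out
    in_ch <- f
    si <- si + 1L
  }
  if (with_gap) {
    shared_d <- if (!is.null(share)) share$embed_layer else NULL
    embed <- ly_dense(in_ch, hyper$embed, bias = hyper$bias, share = shared_d)
    layers <- c(layers, list(ly_gap(), embed, ly_relu()))
    list(layers = layers, out_T = 1L, out_ch = hyper$embed,
         embed_layer = embed, in_shape = sh)
  } else {
    list(layers = layers, out_T = T, out_ch = in_ch, in_shape = sh)
  }
}

build_head <- function(n_in, units, n_classes, dropout, bias) {
  layers <- list()
  for (u in units) {
    layers <- c(layers, list(ly_dense(n_in, u, bias = bias), ly_relu()))
    if (dropout > 0) layers <- c(layers, list(ly_dropout(dropout)))
    n_in <- u
  }
  c(layers, list(ly_dense(n_in, n_classes, bias = bias)))
}

#' Build a neural-network model from a specification
#'
#' Multi-stream families use one convolutional encoder per modality
#' (streams that repeat a modality share encoder weights), feature-level
#' fusion by concatenation of per-stream embeddings and an MLP softmax
#' head.  `cnn_lstm` pools each stream's convolutional features onto a
#' common temporal grid, concatenates them channel-wise and reads out the
#' last LSTM state.  `tcn` stacks four dilated causal convolution blocks
#' (12/24/48/96 filters) with a dense layer of 100 units; `gru` stacks
#' three bidirectional GRU layers (128/256/256 units) with dense layers
#' of 512/256/128 units; `transformer` applies encoder blocks (multi-head
#' self-attention + feed-forward with residual connections and layer
#' normalization) followed by global average pooling.
#'
#' Hyperparameters are overridable through `spec$hyper`; notable knobs:
#' `filters`, `kernel`, `stride`, `dropout`, `embed`, `head`, `bias`
#' (set `FALSE` for relevance-conservation analyses) and `shapes` (named
#' list of `c(T, C)` input shapes, defaulting to the modality registry;
#' use [decimated_shapes()] together with [stack_inputs()]'s `decimate`
#' to train on temporally decimated tensors).
#'
#' @param spec a [model_spec()] with a neural family.
#' @param n_classes number of output classes (default 4 speed classes).
#' @param seed seed for weight initialisation.
#' @return A `gait_network`.
#' @export
build_model <- function(spec, n_classes = 4L, seed = 42L) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family %in% baseline_families) {
    stop(sprintf("family '%s' is a classical baseline; use fit_baseline()",
                 spec$family), call. = FALSE)
  }
  hyper <- utils::modifyList(default_hyper(spec$family), spec$hyper)
  with_seed(derive_seed(seed, 997), {
    switch(spec$family,
      single_cnn = , dual_cnn = , quads_cnn = , fusion_cnn = {
        built <- list()
        streams <- list()
        for (m in spec$modalities) {
          share <- built[[m]]
          st <- build_conv_stream(m, hyper, with_gap = TRUE, share = share)
          if (is.null(share)) built[[m]] <- st
          streams[[length(streams) + 1L]] <-
            list(modality = m, layers = st$layers, in_shape = st$in_shape)
        }
        n_in <- hyper$embed * length(streams)
        head <- build_head(n_in, hyper$head, n_classes, hyper$dropout,
                           hyper$bias)
        new_network(streams, head, "vector_concat", spec$family, n_classes,
                    spec)
      },
      cnn_lstm = {
        streams <- list()
        total_ch <- 0L
        for (m in spec$modalities) {
          st <- build_conv_stream(m, hyper, with_gap = FALSE)
          st$layers <- c(st$layers, list(ly_adapool(hyper$seq_len)))
          streams[[length(streams) + 1L]] <-
            list(modality = m, layers = st$layers, in_shape = st$in_shape)
          total_ch <- total_ch + st$out_ch
        }
        head <- c(list(ly_lstm(total_ch, hyper$lstm_hidden)),
                  build_head(hyper$lstm_hidden, hyper$head, n_classes,
                             hyper$dropout, hyper$bias))
        new_network(streams, head, "seq_concat", spec$family, n_classes, spec)
      },
      tcn = {
        m <- spec$modalities
        sh <- input_shape(m, hyper)
        layers <- list()
        T <- sh[1]; in_ch <- sh[2]
        for (b in seq_along(hyper$filters)) {
          conv <- ly_conv1d(in_ch, hyper$filters[b], hyper$kernel,
                            stride = 1L, dilation = hyper$dilations[b],
                            causal = TRUE, bias = hyper$bias)
          layers <- c(layers, list(conv, ly_relu()))
          if (hyper$dropout > 0) {
            layers <- c(layers, list(ly_dropout(hyper$dropout)))
          }
          in_ch <- hyper$filters[b]
        }
        layers <- c(layers, list(ly_flatten()))
        head <- build_head(T * in_ch, hyper$dense, n_classes,
                           hyper$dropout, hyper$bias)
        new_network(list(list(modality = m, layers = layers, in_shape = sh)),
                    head, "none", "tcn", n_classes, spec)
      },
      gru = {
        m <- spec$modalities
        sh <- input_shape(m, hyper)
        layers <- list()
        in_ch <- sh[2]
        u <- hyper$gru_units
        for (i in seq_along(u)) {
          last <- i == length(u)
          layers <- c(layers, list(
            ly_bigru(in_ch, u[i], return_sequences = !last)))
          if (hyper$dropout > 0 && !last) {
            layers <- c(layers, list(ly_dropout(hyper$dropout)))
          }
          in_ch <- 2L * u[i]
        }
        head <- build_head(in_ch, hyper$head, n_classes, hyper$dropout,
                           hyper$bias)
        new_network(list(list(modality = m, layers = layers, in_shape = sh)),
                    head, "none", "gru", n_classes, spec)
      },
      transformer = {
        m <- spec$modalities
        sh <- input_shape(m, hyper)
        layers <- list()
        layers <- c(layers, list(
          ly_conv1d(sh[2], hyper$d_model, 1L, bias = TRUE)))  # projection
        for (b in seq_len(hyper$n_blocks)) {
          layers <- c(layers, list(
            ly_transformer(hyper$d_model, hyper$n_heads, hyper$d_ff)))
        }
        layers <- c(layers, list(ly_gap()))
        head <- build_head(hyper$d_model, hyper$head, n_classes,
                           hyper$dropout, bias = TRUE)
        new_network(list(list(modality = m, layers = layers, in_shape = sh)),
                    head, "none", "transformer", n_classes, spec)
      },
      stop(sprintf("unknown family '%s'", spec$family), call. = FALSE)
    )
  })
}

# --- classical baselines ----------------------------------------------------

#' Flatten trials of one modality into 1-D feature vectors
#'
#' Optionally block-averages the time axis by `decimate` before
#' flattening (time-major), keeping the vectors at a size classical
#' discriminant classifiers can handle.
#'
#' @param trials list of `gait_trial`s.
#' @param modality modality name.
#' @param decimate temporal block-average factor (1 = none).
#' @return matrix (n_trials x features).
#' @export
flatten_trials <- function(trials, modality, decimate = 1L) {
  mats <- lapply(trials, function(tr) {
    x <- tr[[modality]]
    if (decimate > 1L) {
      T2 <- nrow(x) %/% decimate
      x <- x[seq_len(T2 * decimate), , drop = FALSE]
      x <- matrix(colMeans(matrix(x, decimate, T2 * ncol(x))), T2, ncol(x))
    }
    as.vector(x)
  })
  do.call(rbind, mats)
}

# shrinkage discriminant analysis used when the sample covariance is
# singular: Sigma <- (1 - lambda) * S + lambda * mean(diag(S)) * I
rda_fit <- function(x, y, lambda, pooled = TRUE) {
  classes <- sort(unique(y))
  mus <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  shrink <- function(S) {
    (1 - lambda) * S + lambda * mean(diag(S)) * diag(ncol(S))
  }
  if (pooled) {
    Sw <- Reduce(`+`, lapply(classes, function(cl) {
      xc <- scale(x[y == cl, , drop = FALSE], center = TRUE, scale = FALSE)
      crossprod(xc)
    })) / (nrow(x) - length(classes))
    Si <- list(solve(shrink(Sw)))
    logdet <- list(0)
  } else {
    Si <- lapply(classes, function(cl) {
      xc <- scale(x[y == cl, , drop = FALSE], center = TRUE, scale = FALSE)
      S <- shrink(crossprod(xc) / (sum(y == cl) - 1L))
      solve(S)
    })
    logdet <- lapply(Si, function(M) -determinant(M, logarithm = TRUE)$modulus)
  }
  prior <- as.numeric(table(factor(y, levels = classes))) / length(y)
  list(classes = classes, mus = mus, Si = Si, logdet = logdet,
       prior = prior, pooled = pooled)
}

rda_scores <- function(fit, x) {
  k <- length(fit$classes)
  out <- matrix(0, nrow(x), k)
  for (i in seq_len(k)) {
    Si <- if (fit$pooled) fit$Si[[1]] else fit$Si[[i]]
    ld <- if (fit$pooled) 0 else as.numeric(fit$logdet[[i]])
    xc <- sweep(x, 2L, fit$mus[[i]], `-`)
    out[, i] <- -0.5 * rowSums((xc %*% Si) * xc) - 0.5 * ld +
      log(fit$prior[i])
  }
  out
}

#' Fit a classical baseline classifier on flattened vectors
#'
#' LDA and QDA go through \pkg{MASS}; SVM (radial kernel) through
#' \pkg{e1071}.  When the within-class covariance is singular — common
#' for flattened gait tensors where features outnumber trials — LDA/QDA
#' fail; set `regularize` to a shrinkage weight in (0, 1] to fall back to
#' a shrinkage discriminant (covariance shrunk toward a scaled identity),
#' or reduce the dimension first (see [flatten_trials()]'s `decimate`).
#'
#' @param kind `"lda"`, `"qda"` or `"svm"`.
#' @param x numeric matrix (samples x features).
#' @param y integer class labels (0-based) or factor.
#' @param regularize shrinkage weight for the singular-covariance
#'   fallback; 0 (default) disables it.
#' @return A `gait_baseline` with a [predict()] method
#'   (`type = "class"` or `"prob"`).
#' @export
fit_baseline <- function(kind = c("lda", "qda", "svm"), x, y,
                         regularize = 0) {
  kind <- match.arg(kind)
  assert_that(is.matrix(x) && nrow(x) == length(y),
              "x must be a matrix with one row per label")
  yf <- factor(y)
  fit <- switch(kind,
    lda = , qda = {
      fn <- if (kind == "lda") MASS::lda else MASS::qda
      res <- tryCatch(
        withCallingHandlers(
          fn(x, grouping = yf),
          warning = function(w) {
            if (grepl("collinear", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          }),
        error = function(e) e)
      if (inherits(res, "error")) {
        if (regularize > 0) {
          rda_fit(x, as.integer(yf), regularize, pooled = kind == "lda")
        } else {
          stop(sprintf(
            paste("%s: covariance estimate is singular (%s).",
                  "Reduce the feature dimension (flatten_trials(decimate=))",
                  "or set regularize > 0 for a shrinkage discriminant."),
            kind, conditionMessage(res)), call. = FALSE)
        }
      } else {
        res
      }
    },
    svm = e1071::svm(x, yf, kernel = "radial", probability = TRUE)
  )
  structure(list(kind = kind, fit = fit, levels = levels(yf)),
            class = "gait_baseline")
}

#' @export
predict.gait_baseline <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  f <- object$fit
  if (is.list(f) && !is.null(f$mus)) {  # shrinkage discriminant
    sc <- rda_scores(f, newdata)
    if (type == "class") {
      return(object$levels[max.col(sc)])
    }
    p <- exp(sc - apply(sc, 1L, max))
    p <- p / rowSums(p)
    colnames(p) <- object$levels
    return(p)
  }
  if (object$kind == "svm") {
    pr <- stats::predict(f, newdata, probability = TRUE)
    if (type == "class") return(as.character(pr))
    p <- attr(pr, "probabilities")
    return(p[, object$levels, drop = FALSE])
  }
  pr <- stats::predict(f, newdata)
  if (type == "class") as.character(pr$class) else pr$posterior
}
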