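# Minimal 1-D neural-network layer engine.
#
# Every layer is an environment holding its configuration, parameter
# environments and forward caches.  Forward/backward passes are explicit
# (no autodiff): the same per-layer records that make backpropagation
# possible also expose the activations and pre-activations that
# layer-wise relevance propagation needs.  Batched sequence data travel
# through conv layers as a "rows matrix": a (T*N) x C matrix whose rows
# are ordered time-fastest within sample; vector stages (after global
# pooling or flattening) are plain (N x F) matrices.

# --- batch containers -------------------------------------------------------

rm_batch <- function(x, T, N) list(x = x, T = as.integer(T), N = as.integer(N))

# array (T, C, N) -> rows matrix
rm_from_array <- function(a) {
  d <- dim(a)
  rm_batch(matrix(aperm(a, c(1L, 3L, 2L)), d[1] * d[3], d[2]), d[1], d[3])
}

# rows matrix -> array (T, C, N)
rm_to_array <- function(b) {
  aperm(array(b$x, c(b$T, b$N, ncol(b$x))), c(1L, 3L, 2L))
}

# --- parameters -------------------------------------------------------------

.gx_counter <- new.env(parent = emptyenv())
.gx_counter$n <- 0L

new_param <- function(value) {
  e <- new.env(parent = emptyenv())
  .gx_counter$n <- .gx_counter$n + 1L
  e$id <- .gx_counter$n
  e$W <- value
  e$g <- array(0, dim = dim(value) %||% length(value))
  e$m <- NULL  # Adam state, lazily created
  e$v <- NULL
  class(e) <- "gx_param"
  e
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

zero_grads <- function(params) {
  for (p in params) p$g[] <- 0
  invisible(NULL)
}

# --- layer constructors -----------------------------------------------------

new_layer <- function(type, config = list(), params = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$config <- config
  e$params <- params
  e$cache <- list()
  class(e) <- "gx_layer"
  e
}

ly_conv1d <- function(in_ch, filters, kernel, stride = 1L, dilation = 1L,
                      causal = FALSE, bias = TRUE, share = NULL) {
  params <- if (!is.null(share)) {
    share$params
  } else {
    p <- list(W = new_param(glorot(kernel * in_ch, filters)))
    if (bias) p$b <- new_param(numeric(filters))
    p
  }
  new_layer("conv1d",
            list(in_ch = in_ch, filters = filters, kernel = as.integer(kernel),
                 stride = as.integer(stride), dilation = as.integer(dilation),
                 causal = causal, bias = bias),
            params)
}

ly_dense <- function(n_in, n_out, bias = TRUE, share = NULL) {
  params <- if (!is.null(share)) {
    share$params
  } else {
    p <- list(W = new_param(glorot(n_in, n_out)))
    if (bias) p$b <- new_param(numeric(n_out))
    p
  }
  new_layer("dense", list(n_in = n_in, n_out = n_out, bias = bias), params)
}

ly_relu <- function() new_layer("relu")
ly_dropout <- function(rate) new_layer("dropout", list(rate = rate))
ly_pool <- function(size, mode = c("avg", "max")) {
  new_layer("pool", list(size = as.integer(size), mode = match.arg(mode)))
}
ly_gap <- function() new_layer("gap")
ly_flatten <- function() new_layer("flatten")
# average pooling onto a fixed number of output bins (handles unequal
# stream lengths before sequence fusion)
ly_adapool <- function(out_len) new_layer("adapool",
                                          list(out_len = as.integer(out_len)))

# --- conv utilities ---------------------------------------------------------

conv_geometry <- function(cfg, T) {
  lp <- if (cfg$causal) (cfg$kernel - 1L) * cfg$dilation else 0L
  T_p <- T + lp
  span <- (cfg$kernel - 1L) * cfg$dilation + 1L
  T_out <- (T_p - span) %/% cfg$stride + 1L
  assert_that(T_out >= 1L, sprintf(
    "conv1d: input of %d frames too short for kernel %d (dilation %d)",
    T, cfg$kernel, cfg$dilation))
  list(lp = lp, T_p = T_p, T_out = T_out)
}

# expand rows matrix into the im2col matrix (T_out*N, kernel*in_ch)
conv_im2col <- function(x, T, N, cfg, geo) {
  k <- cfg$kernel
  C <- ncol(x)
  if (geo$lp > 0L) {
    xp <- matrix(0, geo$T_p * N, C)
    tgt <- rep(geo$lp + seq_len(T), N) +
      rep((0:(N - 1L)) * geo$T_p, each = T)
    xp[tgt, ] <- x
    x <- xp
  }
  I <- outer(0:(geo$T_out - 1L) * cfg$stride,
             0:(k - 1L) * cfg$dilation, `+`) + 1L   # T_out x k
  vecI <- as.vector(I)
  idx <- rep(vecI, N) + rep((0:(N - 1L)) * geo$T_p, each = length(vecI))
  A <- array(x[idx, , drop = FALSE], c(geo$T_out, k, N, C))
  list(col = matrix(aperm(A, c(1L, 3L, 2L, 4L)), geo$T_out * N, k * C),
       idx = idx)
}

# scatter-add a (T_out*N, kernel*in_ch) matrix back onto the input grid
conv_col2im <- function(m, T, N, C, cfg, geo, idx) {
  k <- cfg$kernel
  A <- aperm(array(m, c(geo$T_out, N, k, C)), c(1L, 3L, 2L, 4L))
  rows <- matrix(A, geo$T_out * k * N, C)
  g <- rowsum(rows, group = idx)
  out <- matrix(0, geo$T_p * N, C)
  out[as.integer(rownames(g)), ] <- g
  if (geo$lp > 0L) {
    keep <- rep(geo$lp + seq_len(T), N) + rep((0:(N - 1L)) * geo$T_p, each = T)
    out <- out[keep, , drop = FALSE]
  }
  out
}

# --- forward ----------------------------------------------------------------

layer_forward <- function(layer, input, train = FALSE) {
  cfg <- layer$config
  switch(layer$type,
    conv1d = {
      geo <- conv_geometry(cfg, input$T)
      cols <- conv_im2col(input$x, input$T, input$N, cfg, geo)
      z <- cols$col %*% layer$params$W$W
      if (cfg$bias) z <- sweep(z, 2L, layer$params$b$W, `+`)
      layer$cache <- list(col = cols$col, idx = cols$idx, geo = geo,
                          T_in = input$T, N = input$N, z = z)
      rm_batch(z, geo$T_out, input$N)
    },
    dense = {
      x <- input
      z <- x %*% layer$params$W$W
      if (cfg$bias) z <- sweep(z, 2L, layer$params$b$W, `+`)
      layer$cache <- list(x = x, z = z)
      z
    },
    relu = {
      is_rm <- is.list(input)
      x <- if (is_rm) input$x else input
      y <- pmax(x, 0)
      layer$cache <- list(mask = x > 0, is_rm = is_rm)
      if (is_rm) rm_batch(y, input$T, input$N) else y
    },
    dropout = {
      is_rm <- is.list(input)
      x <- if (is_rm) input$x else input
      if (train && cfg$rate > 0) {
        keep <- 1 - cfg$rate
        mask <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) < keep) / keep
        layer$cache <- list(mask = mask, is_rm = is_rm)
        x <- x * mask
      } else {
        layer$cache <- list(mask = NULL, is_rm = is_rm)
      }
      if (is_rm) rm_batch(x, input$T, input$N) else x
    },
    pool = {
      p <- cfg$size
      T <- input$T; N <- input$N; C <- ncol(input$x)
      T_out <- T %/% p
      assert_that(T_out >= 1L, "pool: window larger than the sequence")
      keep <- rep(seq_len(T_out * p), N) + rep((0:(N - 1L)) * T, each = T_out * p)
      bk <- input$x[keep, , drop = FALSE]
      if (cfg$mode == "avg") {
        v <- colMeans(matrix(bk, p, T_out * N * C))
        out <- matrix(v, T_out * N, C)
        layer$cache <- list(T_in = T, N = N, C = C, T_out = T_out, keep = keep)
      } else {
        out <- bk[seq(1L, nrow(bk), by = p), , drop = FALSE]
        amax <- matrix(1L, T_out * N, C)
        if (p > 1L) {
          for (j in 2:p) {
            s <- bk[seq(j, nrow(bk), by = p), , drop = FALSE]
            upd <- s > out
            out[upd] <- s[upd]
            amax[upd] <- j
          }
        }
        layer$cache <- list(T_in = T, N = N, C = C, T_out = T_out,
                            keep = keep, amax = amax, bk = bk)
      }
      rm_batch(out, T_out, N)
    },
    gap = {
      T <- input$T; N <- input$N
      grp <- rep(seq_len(N), each = T)
      out <- rowsum(input$x, group = grp) / T
      layer$cache <- list(T_in = T, N = N, x = input$x)
      out
    },
    adapool = {
      T <- input$T; N <- input$N; L <- cfg$out_len
      assert_that(L <= T, "adapool: more output bins than frames")
      bin <- pmin(floor((seq_len(T) - 1L) * L / T) + 1L, L)
      grp <- rep(bin, N) + rep((0:(N - 1L)) * L, each = T)
      counts <- tabulate(bin, nbins = L)
      out <- rowsum(input$x, group = grp) / counts  # recycles per sample
      layer$cache <- list(T_in = T, N = N, bin = bin, counts = counts)
      rm_batch(out, L, N)
    },
    flatten = {
      T <- input$T; N <- input$N; C <- ncol(input$x)
      A <- array(input$x, c(T, N, C))
      out <- matrix(aperm(A, c(2L, 1L, 3L)), N, T * C)
      layer$cache <- list(T_in = T, N = N, C = C)
      out
    },
    lstm = lstm_forward(layer, input),
    bigru = bigru_forward(layer, input),
    transformer_block = transformer_forward(layer, input, train),
    stop(sprintf("unsupported layer type '%s'", layer$type), call. = FALSE)
  )
}

# --- backward ---------------------------------------------------------------

relu_back <- function(grad, mask, mode) {
  switch(mode,
    standard = grad * mask,
    guided   = grad * mask * (grad > 0),
    deconv   = grad * (grad > 0),
    stop("unknown relu mode"))
}

layer_backward <- function(layer, grad, relu_mode = "standard") {
  cfg <- layer$config
  cc <- layer$cache
  switch(layer$type,
    conv1d = {
      g <- if (is.list(grad)) grad$x else grad
      layer$params$W$g <- layer$params$W$g + crossprod(cc$col, g)
      if (cfg$bias) layer$params$b$g <- layer$params$b$g + colSums(g)
      dcol <- g %*% t(layer$params$W$W)
      dx <- conv_col2im(dcol, cc$T_in, cc$N, cfg$in_ch, cfg, cc$geo, cc$idx)
      rm_batch(dx, cc$T_in, cc$N)
    },
    dense = {
      layer$params$W$g <- layer$params$W$g + crossprod(cc$x, grad)
      if (cfg$bias) layer$params$b$g <- layer$params$b$g + colSums(grad)
      grad %*% t(layer$params$W$W)
    },
    relu = {
      g <- if (cc$is_rm) grad$x else grad
      out <- relu_back(g, cc$mask, relu_mode)
      if (cc$is_rm) rm_batch(out, grad$T, grad$N) else out
    },
    dropout = {
      g <- if (cc$is_rm) grad$x else grad
      if (!is.null(cc$mask)) g <- g * cc$mask
      if (cc$is_rm) rm_batch(g, grad$T, grad$N) else g
    },
    pool = {
      p <- cfg$size
      g <- grad$x
      if (cfg$mode == "avg") {
        dbk <- matrix(rep(as.vector(g) / p, each = p),
                      cc$T_out * p * cc$N, cc$C)
      } else {
        dbk <- matrix(0, cc$T_out * p * cc$N, cc$C)
        for (j in seq_len(p)) {
          sel <- cc$amax == j
          rows_j <- seq(j, nrow(dbk), by = p)
          tmp <- matrix(0, cc$T_out * cc$N, cc$C)
          tmp[sel] <- g[sel]
          dbk[rows_j, ] <- tmp
        }
      }
      dx <- matrix(0, cc$T_in * cc$N, cc$C)
      dx[cc$keep, ] <- dbk
      rm_batch(dx, cc$T_in, cc$N)
    },
    gap = {
      dx <- grad[rep(seq_len(cc$N), each = cc$T_in), , drop = FALSE] / cc$T_in
      rm_batch(dx, cc$T_in, cc$N)
    },
    adapool = {
      L <- cfg$out_len
      idx <- rep(cc$bin, cc$N) + rep((0:(cc$N - 1L)) * L, each = cc$T_in)
      dx <- grad$x[idx, , drop = FALSE] / cc$counts[rep(cc$bin, cc$N)]
      rm_batch(dx, cc$T_in, cc$N)
    },
    flatten = {
      A <- array(grad, c(cc$N, cc$T_in, cc$C))
      rm_batch(matrix(aperm(A, c(2L, 1L, 3L)), cc$T_in * cc$N, cc$C),
               cc$T_in, cc$N)
    },
    lstm = lstm_backward(layer, grad, relu_mode),
    bigru = bigru_backward(layer, grad, relu_mode),
    transformer_block = transformer_backward(layer, grad, relu_mode),
    stop(sprintf("unsupported layer type '%s'", layer$type), call. = FALSE)
  )
}

layer_params <- function(layer) {
  Filter(function(p) inherits(p, "gx_param"), layer$params)
}
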