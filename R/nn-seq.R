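# Sequence layers: LSTM (last-state readout), bidirectional GRU and a
# Transformer encoder block.  All operate on rows-matrix batches and keep
# the caches needed for exact backpropagation through time.

sigm <- function(x) 1 / (1 + exp(-x))

# rows matrix -> array (T, N, C) with per-timestep (N, C) slices
rm_tnc <- function(b) array(b$x, c(b$T, b$N, ncol(b$x)))
tnc_rm <- function(a) rm_batch(matrix(a, dim(a)[1] * dim(a)[2], dim(a)[3]),
                               dim(a)[1], dim(a)[2])
slice_t <- function(a, t) matrix(a[t, , ], dim(a)[2], dim(a)[3])

# --- LSTM -------------------------------------------------------------------

ly_lstm <- function(in_ch, hidden) {
  Wx <- new_param(glorot(in_ch, 4L * hidden))
  Wh <- new_param(glorot(hidden, 4L * hidden))
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  new_layer("lstm", list(in_ch = in_ch, hidden = hidden),
            list(Wx = Wx, Wh = Wh, b = new_param(b)))
}

lstm_forward <- function(layer, input) {
  H <- layer$config$hidden
  a <- rm_tnc(input)
  T <- dim(a)[1]; N <- dim(a)[2]
  Wx <- layer$params$Wx$W; Wh <- layer$params$Wh$W; b <- layer$params$b$W
  h <- matrix(0, N, H); cstate <- matrix(0, N, H)
  steps <- vector("list", T)
  ii <- 1:H; ff <- (H + 1L):(2L * H); gg <- (2L * H + 1L):(3L * H)
  oo <- (3L * H + 1L):(4L * H)
  for (t in seq_len(T)) {
    xt <- slice_t(a, t)
    A <- xt %*% Wx + h %*% Wh
    A <- sweep(A, 2L, b, `+`)
    i <- sigm(A[, ii, drop = FALSE]); f <- sigm(A[, ff, drop = FALSE])
    g <- tanh(A[, gg, drop = FALSE]); o <- sigm(A[, oo, drop = FALSE])
    c_prev <- cstate
    cstate <- f * c_prev + i * g
    hc <- tanh(cstate)
    steps[[t]] <- list(x = xt, h_prev = h, c_prev = c_prev,
                       i = i, f = f, g = g, o = o, hc = hc)
    h <- o * hc
  }
  layer$cache <- list(steps = steps, T = T, N = N)
  h
}

lstm_backward <- function(layer, grad, relu_mode) {
  cfg <- layer$config; H <- cfg$hidden
  cc <- layer$cache; T <- cc$T; N <- cc$N
  Wx <- layer$params$Wx$W; Wh <- layer$params$Wh$W
  dWx <- layer$params$Wx$g; dWh <- layer$params$Wh$g; db <- layer$params$b$g
  dh <- grad; dc <- matrix(0, N, H)
  dX <- array(0, c(T, N, cfg$in_ch))
  for (t in rev(seq_len(T))) {
    s <- cc$steps[[t]]
    do <- dh * s$hc
    dc <- dc + dh * s$o * (1 - s$hc^2)
    di <- dc * s$g; dg <- dc * s$i; df <- dc * s$c_prev
    dc <- dc * s$f
    dA <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                dg * (1 - s$g^2), do * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$x, dA)
    dWh <- dWh + crossprod(s$h_prev, dA)
    db <- db + colSums(dA)
    dX[t, , ] <- dA %*% t(Wx)
    dh <- dA %*% t(Wh)
  }
  layer$params$Wx$g <- dWx; layer$params$Wh$g <- dWh; layer$params$b$g <- db
  tnc_rm(dX)
}

# --- bidirectional GRU ------------------------------------------------------

gru_params <- function(in_ch, hidden) {
  list(Wx = new_param(glorot(in_ch, 3L * hidden)),
       Wh = new_param(glorot(hidden, 3L * hidden)),
       bx = new_param(numeric(3L * hidden)),
       bh = new_param(numeric(3L * hidden)))
}

ly_bigru <- function(in_ch, hidden, return_sequences = TRUE) {
  pf <- gru_params(in_ch, hidden)
  pb <- gru_params(in_ch, hidden)
  names(pb) <- paste0(names(pb), "_rev")
  new_layer("bigru",
            list(in_ch = in_ch, hidden = hidden,
                 return_sequences = return_sequences),
            c(pf, pb))
}

gru_dir_forward <- function(p, a, reverse) {
  T <- dim(a)[1]; N <- dim(a)[2]
  H <- ncol(p$Wh$W) / 3L
  rr <- 1:H; zz <- (H + 1L):(2L * H); nn <- (2L * H + 1L):(3L * H)
  h <- matrix(0, N, H)
  order_t <- if (reverse) rev(seq_len(T)) else seq_len(T)
  h_seq <- array(0, c(T, N, H))
  steps <- vector("list", T)
  for (t in order_t) {
    xt <- slice_t(a, t)
    Ax <- sweep(xt %*% p$Wx$W, 2L, p$bx$W, `+`)
    Ah <- sweep(h %*% p$Wh$W, 2L, p$bh$W, `+`)
    r <- sigm(Ax[, rr, drop = FALSE] + Ah[, rr, drop = FALSE])
    z <- sigm(Ax[, zz, drop = FALSE] + Ah[, zz, drop = FALSE])
    n <- tanh(Ax[, nn, drop = FALSE] + r * Ah[, nn, drop = FALSE])
    h_prev <- h
    h <- (1 - z) * n + z * h_prev
    steps[[t]] <- list(x = xt, h_prev = h_prev, r = r, z = z, n = n,
                       Ah_n = Ah[, nn, drop = FALSE])
    h_seq[t, , ] <- h
  }
  list(h_seq = h_seq, steps = steps, last = h, order_t = order_t)
}

gru_dir_backward <- function(p, fw, dh_seq, dlast, in_ch) {
  T <- dim(fw$h_seq)[1]; N <- dim(fw$h_seq)[2]
  H <- ncol(p$Wh$W) / 3L
  dh <- dlast
  dX <- array(0, c(T, N, in_ch))
  dWx <- p$Wx$g; dWh <- p$Wh$g; dbx <- p$bx$g; dbh <- p$bh$g
  for (t in rev(fw$order_t)) {
    s <- fw$steps[[t]]
    dh <- dh + matrix(dh_seq[t, , ], N, H)
    dz <- dh * (s$h_prev - s$n)
    dn <- dh * (1 - s$z)
    dh_prev <- dh * s$z
    dAn <- dn * (1 - s$n^2)
    dr <- dAn * s$Ah_n
    dAh_n <- dAn * s$r
    dr_pre <- dr * s$r * (1 - s$r)
    dz_pre <- dz * s$z * (1 - s$z)
    dAx <- cbind(dr_pre, dz_pre, dAn)
    dAh <- cbind(dr_pre, dz_pre, dAh_n)
    dWx <- dWx + crossprod(s$x, dAx); dbx <- dbx + colSums(dAx)
    dWh <- dWh + crossprod(s$h_prev, dAh); dbh <- dbh + colSums(dAh)
    dX[t, , ] <- dX[t, , ] + dAx %*% t(p$Wx$W)
    dh <- dh_prev + dAh %*% t(p$Wh$W)
  }
  p$Wx$g <- dWx; p$Wh$g <- dWh; p$bx$g <- dbx; p$bh$g <- dbh
  dX
}

bigru_forward <- function(layer, input) {
  cfg <- layer$config
  a <- rm_tnc(input)
  pf <- layer$params[c("Wx", "Wh", "bx", "bh")]
  pb <- layer$params[c("Wx_rev", "Wh_rev", "bx_rev", "bh_rev")]
  names(pb) <- c("Wx", "Wh", "bx", "bh")
  fw <- gru_dir_forward(pf, a, reverse = FALSE)
  bw <- gru_dir_forward(pb, a, reverse = TRUE)
  layer$cache <- list(fw = fw, bw = bw, T = dim(a)[1], N = dim(a)[2])
  if (cfg$return_sequences) {
    H <- cfg$hidden
    out <- array(0, c(dim(a)[1], dim(a)[2], 2L * H))
    out[, , 1:H] <- fw$h_seq
    out[, , (H + 1L):(2L * H)] <- bw$h_seq
    tnc_rm(out)
  } else {
    cbind(fw$last, bw$last)
  }
}

bigru_backward <- function(layer, grad, relu_mode) {
  cfg <- layer$config; H <- cfg$hidden
  cc <- layer$cache; T <- cc$T; N <- cc$N
  pf <- layer$params[c("Wx", "Wh", "bx", "bh")]
  pb <- layer$params[c("Wx_rev", "Wh_rev", "bx_rev", "bh_rev")]
  names(pb) <- c("Wx", "Wh", "bx", "bh")
  zero_seq <- array(0, c(T, N, H))
  zero_last <- matrix(0, N, H)
  if (cfg$return_sequences) {
    ga <- rm_tnc(grad)
    dfw <- array(ga[, , 1:H], c(T, N, H))
    dbw <- array(ga[, , (H + 1L):(2L * H)], c(T, N, H))
    dX <- gru_dir_backward(pf, cc$fw, dfw, zero_last, cfg$in_ch) +
      gru_dir_backward(pb, cc$bw, dbw, zero_last, cfg$in_ch)
  } else {
    dX <- gru_dir_backward(pf, cc$fw, zero_seq,
                           grad[, 1:H, drop = FALSE], cfg$in_ch) +
      gru_dir_backward(pb, cc$bw, zero_seq,
                       grad[, (H + 1L):(2L * H), drop = FALSE], cfg$in_ch)
  }
  tnc_rm(dX)
}

# --- Transformer encoder block ---------------------------------------------

ly_transformer <- function(d_model, n_heads, d_ff) {
  assert_that(d_model %% n_heads == 0L, "d_model must be divisible by n_heads")
  new_layer("transformer_block",
            list(d = d_model, heads = n_heads, d_ff = d_ff),
            list(Wq = new_param(glorot(d_model, d_model)),
                 Wk = new_param(glorot(d_model, d_model)),
                 Wv = new_param(glorot(d_model, d_model)),
                 Wo = new_param(glorot(d_model, d_model)),
                 W1 = new_param(glorot(d_model, d_ff)),
                 b1 = new_param(numeric(d_ff)),
                 W2 = new_param(glorot(d_ff, d_model)),
                 b2 = new_param(numeric(d_model)),
                 g1 = new_param(rep(1, d_model)),
                 o1 = new_param(numeric(d_model)),
                 g2 = new_param(rep(1, d_model)),
                 o2 = new_param(numeric(d_model))))
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, fwd, g) {
  d <- ncol(dy)
  dxhat <- sweep(dy, 2L, g, `*`)
  dg <- colSums(dy * fwd$xhat)
  db <- colSums(dy)
  dx <- (dxhat - rowMeans(dxhat) -
           fwd$xhat * rowMeans(dxhat * fwd$xhat)) * fwd$inv
  list(dx = dx, dg = dg, db = db)
}

transformer_forward <- function(layer, input, train) {
  cfg <- layer$config; p <- layer$params
  d <- cfg$d; h <- cfg$heads; dk <- d %/% h
  x <- input$x; T <- input$T; N <- input$N
  Q <- x %*% p$Wq$W; K <- x %*% p$Wk$W; V <- x %*% p$Wv$W
  Hmat <- matrix(0, T * N, d)
  attn <- vector("list", N)
  for (s in seq_len(N)) {
    rows <- ((s - 1L) * T + 1L):(s * T)
    heads <- vector("list", h)
    for (j in seq_len(h)) {
      colsj <- ((j - 1L) * dk + 1L):(j * dk)
      Qh <- Q[rows, colsj, drop = FALSE]
      Kh <- K[rows, colsj, drop = FALSE]
      S <- Qh %*% t(Kh) / sqrt(dk)
      S <- S - apply(S, 1L, max)
      P <- exp(S); P <- P / rowSums(P)
      Hmat[rows, colsj] <- P %*% V[rows, colsj, drop = FALSE]
      heads[[j]] <- P
    }
    attn[[s]] <- heads
  }
  O <- Hmat %*% p$Wo$W
  U <- x + O
  ln1 <- layernorm_fwd(U, p$g1$W, p$o1$W)
  F1pre <- sweep(ln1$y %*% p$W1$W, 2L, p$b1$W, `+`)
  F1 <- pmax(F1pre, 0)
  F2 <- sweep(F1 %*% p$W2$W, 2L, p$b2$W, `+`)
  V2 <- ln1$y + F2
  ln2 <- layernorm_fwd(V2, p$g2$W, p$o2$W)
  layer$cache <- list(x = x, T = T, N = N, Q = Q, K = K, V = V,
                      attn = attn, Hmat = Hmat, ln1 = ln1, F1pre = F1pre,
                      F1 = F1, ln2 = ln2)
  rm_batch(ln2$y, T, N)
}

transformer_backward <- function(layer, grad, relu_mode) {
  cfg <- layer$config; p <- layer$params; cc <- layer$cache
  d <- cfg$d; h <- cfg$heads; dk <- d %/% h
  T <- cc$T; N <- cc$N
  dy <- grad$x
  l2 <- layernorm_bwd(dy, cc$ln2, p$g2$W)
  p$g2$g <- p$g2$g + l2$dg; p$o2$g <- p$o2$g + l2$db
  dV2 <- l2$dx
  dF2 <- dV2
  p$W2$g <- p$W2$g + crossprod(cc$F1, dF2)
  p$b2$g <- p$b2$g + colSums(dF2)
  dF1 <- relu_back(dF2 %*% t(p$W2$W), cc$F1pre > 0, relu_mode)
  p$W1$g <- p$W1$g + crossprod(cc$ln1$y, dF1)
  p$b1$g <- p$b1$g + colSums(dF1)
  dY1 <- dV2 + dF1 %*% t(p$W1$W)
  l1 <- layernorm_bwd(dY1, cc$ln1, p$g1$W)
  p$g1$g <- p$g1$g + l1$dg; p$o1$g <- p$o1$g + l1$db
  dU <- l1$dx
  dx <- dU
  dO <- dU
  p$Wo$g <- p$Wo$g + crossprod(cc$Hmat, dO)
  dH <- dO %*% t(p$Wo$W)
  dQ <- matrix(0, T * N, d); dK <- dQ; dV <- dQ
  for (s in seq_len(N)) {
    rows <- ((s - 1L) * T + 1L):(s * T)
    for (j in seq_len(h)) {
      colsj <- ((j - 1L) * dk + 1L):(j * dk)
      P <- cc$attn[[s]][[j]]
      dHh <- dH[rows, colsj, drop = FALSE]
      Vh <- cc$V[rows, colsj, drop = FALSE]
      dP <- dHh %*% t(Vh)
      dV[rows, colsj] <- crossprod(P, dHh)
      dS <- P * (dP - rowSums(dP * P))
      dQ[rows, colsj] <- dS %*% cc$K[rows, colsj, drop = FALSE] / sqrt(dk)
      dK[rows, colsj] <- crossprod(dS, cc$Q[rows, colsj, drop = FALSE]) / sqrt(dk)
    }
  }
  p$Wq$g <- p$Wq$g + crossprod(cc$x, dQ)
  p$Wk$g <- p$Wk$g + crossprod(cc$x, dK)
  p$Wv$g <- p$Wv$g + crossprod(cc$x, dV)
  dx <- dx + dQ %*% t(p$Wq$W) + dK %*% t(p$Wk$W) + dV %*% t(p$Wv$W)
  rm_batch(dx, T, N)
}
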