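# The layer engine has no autodiff: every backward pass is hand-derived,
# so each layer family is checked against central finite differences.

fd_check <- function(layers, T = 12L, C = 3L, N = 2L, tol = 1e-6) {
  set.seed(42)
  x <- array(rnorm(T * C * N), c(T, C, N))
  fwd_scalar <- function(xa) {
    cur <- gaitxai:::rm_from_array(xa)
    for (ly in layers) cur <- gaitxai:::layer_forward(ly, cur, train = FALSE)
    out <- if (is.list(cur)) cur$x else cur
    sum(out * seq_along(out) / length(out))
  }
  cur <- gaitxai:::rm_from_array(x)
  for (ly in layers) cur <- gaitxai:::layer_forward(ly, cur, train = FALSE)
  out <- if (is.list(cur)) cur$x else cur
  dout <- matrix(seq_along(out) / length(out), nrow(out), ncol(out))
  g <- if (is.list(cur)) gaitxai:::rm_batch(dout, cur$T, cur$N) else dout
  params <- unlist(lapply(layers, gaitxai:::layer_params), recursive = FALSE)
  gaitxai:::zero_grads(params)
  for (ly in rev(layers)) g <- gaitxai:::layer_backward(ly, g, "standard")
  ga <- gaitxai:::rm_to_array(g)
  h <- 1e-5
  for (i in sample(length(x), 12)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    expect_equal(ga[i], (fwd_scalar(xp) - fwd_scalar(xm)) / (2 * h),
                 tolerance = tol)
  }
  for (p in params) {
    for (i in sample(length(p$W), min(4, length(p$W)))) {
      w0 <- p$W[i]
      p$W[i] <- w0 + h; fp <- fwd_scalar(x)
      p$W[i] <- w0 - h; fm <- fwd_scalar(x)
      p$W[i] <- w0
      expect_equal(p$g[i], (fp - fm) / (2 * h), tolerance = tol)
    }
  }
}

test_that("convolution and pooling backward passes match finite differences", {
  fd_check(list(gaitxai:::ly_conv1d(3, 4, 3, stride = 2)))
  fd_check(list(gaitxai:::ly_conv1d(3, 4, 3, dilation = 2, causal = TRUE)))
  fd_check(list(gaitxai:::ly_conv1d(3, 4, 3), gaitxai:::ly_relu(),
                gaitxai:::ly_pool(2, "avg")))
  fd_check(list(gaitxai:::ly_conv1d(3, 4, 3), gaitxai:::ly_pool(2, "max")))
  fd_check(list(gaitxai:::ly_conv1d(3, 4, 3), gaitxai:::ly_gap(),
                gaitxai:::ly_dense(4, 5)))
  fd_check(list(gaitxai:::ly_conv1d(3, 4, 3), gaitxai:::ly_flatten(),
                gaitxai:::ly_dense(40, 5)))
  fd_check(list(gaitxai:::ly_adapool(5)))
})

test_that("recurrent and attention backward passes match finite differences", {
  fd_check(list(gaitxai:::ly_lstm(3, 4)))
  fd_check(list(gaitxai:::ly_bigru(3, 3, TRUE)))
  fd_check(list(gaitxai:::ly_bigru(3, 3, FALSE)))
  fd_check(list(gaitxai:::ly_conv1d(3, 4, 1),
                gaitxai:::ly_transformer(4, 2, 6)), tol = 1e-5)
})

test_that("model specifications enforce the family/modality contract", {
  expect_error(model_spec("single_cnn", c("markers", "emg")), "exactly 1")
  expect_error(model_spec("quads_cnn", "markers"), "exactly 4")
  expect_error(model_spec("dual_cnn", c("markers", "emg", "grf")), "exactly 2")
  expect_silent(model_spec("dual_cnn", c("markers", "emg")))
  expect_error(build_model(model_spec("lda", "markers")), "fit_baseline")
  # TCN defaults: four dilated causal blocks with 12/24/48/96 filters
  tcn <- build_model(model_spec("tcn", "emg",
                                list(shapes = list(emg = c(64L, 3L)))))
  convs <- Filter(function(l) l$type == "conv1d", tcn$streams[[1]]$layers)
  expect_equal(vapply(convs, function(l) l$config$filters, integer(1)),
               c(12L, 24L, 48L, 96L))
  expect_equal(vapply(convs, function(l) l$config$dilation, integer(1)),
               c(1L, 2L, 4L, 8L))
  expect_true(all(vapply(convs, function(l) l$config$causal, logical(1))))
})

test_that("every architecture family builds, predicts and learns a step", {
  shapes <- list(markers = c(24L, 4L), grf = c(24L, 3L), emg = c(36L, 3L),
                 fm = c(36L, 3L))
  x <- lapply(shapes, function(s) array(rnorm(prod(s) * 6), c(s, 6L)))
  y <- rep(0:1, 3)
  small <- list(filters = c(3L, 4L), kernel = 3L, stride = 2L, dropout = 0.1,
                embed = 6L, head = 6L, shapes = shapes, seq_len = 4L,
                lstm_hidden = 5L, d_model = 4L, n_heads = 2L, d_ff = 6L,
                n_blocks = 1L, gru_units = c(3L, 4L), dense = 8L)
  fams <- list(
    single_cnn = "markers",
    dual_cnn = c("markers", "emg"),
    quads_cnn = c("markers", "grf", "emg", "fm"),
    fusion_cnn = c("markers", "grf", "emg", "fm"),
    cnn_lstm = c("markers", "grf", "emg", "fm"),
    tcn = "emg", gru = "markers", transformer = "markers")
  for (fam in names(fams)) {
    hy <- small
    if (fam == "tcn") hy$filters <- c(3L, 4L)
    if (fam == "tcn") hy$dilations <- c(1L, 2L)
    net <- build_model(model_spec(fam, fams[[fam]], hy), n_classes = 2L,
                       seed = 7)
    p <- predict_proba(net, x)
    expect_equal(dim(p), c(6L, 2L))
    expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-9)
    expect_true(all(p >= 0))
    train_network(net, x, y, config = train_config(
      max_epochs = 2L, batch_size = 4L, seed = 1))
    expect_equal(nrow(net$history), 2L)
    expect_true(all(is.finite(net$history$train_loss)))
  }
})

test_that("softmax head has one output per speed class", {
  net <- tiny_quads(bias = TRUE)
  p <- predict_proba(net, lapply(tiny_shapes, function(s) {
    array(rnorm(prod(s)), c(s, 1L))
  }))
  expect_equal(ncol(p), 4L)
  expect_error(
    predict_proba(net, list(markers = array(0, c(10, 6, 1)),
                            grf = array(0, c(40, 4, 1)),
                            emg = array(0, c(60, 3, 1)),
                            fm = array(0, c(60, 5, 1)))),
    "expected 40 x 6")
})

test_that("streams repeating a modality share encoder weights", {
  sh <- list(markers = c(24L, 4L))
  net <- build_model(model_spec("dual_cnn", c("markers", "markers"),
                                list(filters = 3L, kernel = 3L,
                                     stride = 1L, dropout = 0, embed = 4L,
                                     head = 4L, shapes = sh)),
                     seed = 1)
  p1 <- gaitxai:::layer_params(net$streams[[1]]$layers[[1]])$W
  p2 <- gaitxai:::layer_params(net$streams[[2]]$layers[[1]])$W
  expect_identical(p1$id, p2$id)
  expect_identical(p1$W, p2$W)
})

test_that("training reproduces with a fixed seed and stops on patience", {
  shapes <- list(markers = c(20L, 3L))
  x <- list(markers = array(rnorm(20 * 3 * 12), c(20L, 3L, 12L)))
  y <- rep(0:1, 6)
  mk <- function() build_model(model_spec(
    "single_cnn", "markers",
    list(filters = 4L, kernel = 3L, stride = 2L, dropout = 0, embed = 4L,
         head = 4L, shapes = shapes)), n_classes = 2L, seed = 9)
  n1 <- mk(); n2 <- mk()
  cfg <- train_config(max_epochs = 5L, batch_size = 4L, seed = 3)
  train_network(n1, x, y, config = cfg)
  train_network(n2, x, y, config = cfg)
  expect_identical(n1$history, n2$history)
  w1 <- gaitxai:::snapshot_params(gaitxai:::network_params(n1))
  w2 <- gaitxai:::snapshot_params(gaitxai:::network_params(n2))
  expect_identical(w1, w2)
  # zero learning rate: validation loss never improves after the first
  # epoch, so training stops at exactly patience + 1 epochs
  n3 <- mk()
  train_network(n3, x, y, val_inputs = x, val_y = y,
                config = train_config(learning_rate = 0, max_epochs = 100L,
                                      patience = 7L, batch_size = 4L,
                                      seed = 3))
  expect_equal(nrow(n3$history), 8L)
  expect_error(train_network(mk(), list(markers = array(0, c(20, 3, 0))),
                             integer(0)), "empty")
})

test_that("a small CNN reaches high training accuracy on the planted cohort", {
  cohort <- small_cohort()
  std <- standardize_trials(cohort$trials)
  dec <- c(markers = 8L, grf = 8L, emg = 64L, fm = 64L)
  x <- stack_inputs(std$trials, decimate = dec)
  y <- cohort$labels$class
  net <- build_model(model_spec(
    "quads_cnn", c("markers", "grf", "emg", "fm"),
    list(filters = c(8L, 16L), kernel = 5L, stride = 2L, dropout = 0,
         embed = 16L, head = 32L, shapes = decimated_shapes(dec))), seed = 2)
  train_network(net, x, y, config = train_config(max_epochs = 100L, seed = 4))
  acc <- mean(max.col(predict_proba(net, x)) - 1L == y)
  expect_gte(acc, 0.95)
})

test_that("classical baselines fit, predict and fail informatively", {
  set.seed(10)
  # linearly separable blobs
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 6), 50, 2))
  y <- rep(0:1, each = 50)
  fit <- fit_baseline("lda", x, y)
  expect_equal(mean(predict(fit, x) == as.character(y)), 1)
  prob <- predict(fit, x, type = "prob")
  expect_equal(rowSums(prob), rep(1, 100), tolerance = 1e-9)
  # permuted labels: accuracy near chance for 4 balanced classes
  xp <- matrix(rnorm(400 * 3), 400, 3)
  yp <- with(list(), {set.seed(11); sample(rep(0:3, 100))})
  fperm <- fit_baseline("lda", xp, yp)
  acc <- mean(predict(fperm, xp) == as.character(yp))
  expect_lt(abs(acc - 0.25), 0.1)
  # distinct class covariances: QDA beats LDA
  n <- 300
  set.seed(12)
  xa <- matrix(rnorm(2 * n, sd = 0.5), n, 2)
  xb <- matrix(rnorm(2 * n, sd = 3), n, 2)
  xq <- rbind(xa, xb); yq <- rep(0:1, each = n)
  acc_of <- function(kind) {
    f <- fit_baseline(kind, xq, yq)
    mean(predict(f, xq) == as.character(yq))
  }
  expect_gt(acc_of("qda"), acc_of("lda"))
  # singular covariance: actionable error, shrinkage knob works
  xs <- cbind(rnorm(20), rnorm(20))
  xs <- cbind(xs, xs[, 1] + xs[, 2])  # exactly collinear
  ys <- rep(0:1, each = 10)
  expect_error(fit_baseline("qda", xs, ys), "regularize")
  freg <- fit_baseline("qda", xs, ys, regularize = 0.5)
  expect_true(all(predict(freg, xs) %in% c("0", "1")))
  # svm with probabilities
  fs <- fit_baseline("svm", x, y)
  ps <- predict(fs, x, type = "prob")
  expect_equal(colnames(ps), c("0", "1"))
})
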