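# Relevance propagation: analytic single-layer fixtures, conservation
# over random CNNs, and the gradient-family baselines against finite
# differences.

test_that("a one-layer linear trace exposes the expected pre-activation", {
  net <- linear_net(matrix(c(1, 1), 2, 1))
  tr <- forward_trace(net, list(markers = matrix(c(1, 1), 2, 1)))
  expect_equal(tr$logits, 2)
  expect_equal(replay_trace(tr), tr$logits)
})

test_that("z-rule relevance on single linear layers matches hand results", {
  # w = (1, 1), x = (1, 1): symmetric split
  net <- linear_net(matrix(c(1, 1), 2, 1))
  tr <- forward_trace(net, list(markers = matrix(c(1, 1), 2, 1)))
  r <- lrp_backward(tr, 0, rule_config("z"))
  expect_equal(as.vector(r$relevance$markers), c(1, 1))
  # w = (2, 0): all relevance follows the contributing weight
  net2 <- linear_net(matrix(c(2, 0), 2, 1))
  tr2 <- forward_trace(net2, list(markers = matrix(c(1, 1), 2, 1)))
  r2 <- lrp_backward(tr2, 0, rule_config("z"))
  expect_equal(as.vector(r2$relevance$markers), c(2, 0))
})

test_that("the alpha2-beta1 split reproduces the signed decomposition", {
  # w = (2, -1), x = (1, 1): z+ = 2, z- = -1, f = 1
  # R = alpha * (2, 0) / 2 - beta * (0, -1) / (-1) -> (2, -1)
  net <- linear_net(matrix(c(2, -1), 2, 1))
  tr <- forward_trace(net, list(markers = matrix(c(1, 1), 2, 1)))
  r <- lrp_backward(tr, 0, rule_config("alpha_beta", epsilon = 0))
  expect_equal(as.vector(r$relevance$markers), c(2, -1), tolerance = 1e-12)
  expect_equal(r$total, tr$logits[1], tolerance = 1e-12)
})

test_that("z-rule conservation holds on a bias-free ReLU CNN", {
  net <- tiny_quads(bias = FALSE)
  set.seed(21)
  rel_err <- replicate(50, {
    x <- random_tiny_inputs()
    tr <- forward_trace(net, x)
    cls <- which.max(tr$logits) - 1L
    r <- lrp_backward(tr, cls, rule_config("z"))
    abs(r$total - tr$logits[cls + 1]) / abs(tr$logits[cls + 1])
  })
  expect_lt(max(rel_err), 1e-4)
})

test_that("alpha-beta conservation is exact when both signed pools exist", {
  # wide bias-free dense layer: every unit sees positive and negative
  # contributions almost surely
  set.seed(8)
  W <- matrix(rnorm(64 * 4), 64, 4)
  dense <- gaitxai:::ly_dense(64, 4, bias = FALSE)
  dense$params$W$W <- W
  net <- gaitxai:::new_network(
    streams = list(list(modality = "markers",
                        layers = list(gaitxai:::ly_flatten()),
                        in_shape = c(64L, 1L))),
    head = list(dense), merge = "vector_concat", n_classes = 4L)
  for (i in 1:10) {
    x <- matrix(rnorm(64), 64, 1)
    tr <- forward_trace(net, list(markers = x))
    r <- lrp_backward(tr, 2, rule_config("alpha_beta", epsilon = 0))
    expect_equal(r$total, tr$logits[3], tolerance = 1e-10)
  }
})

test_that("the epsilon rule converges monotonically to the z rule", {
  net <- tiny_quads(bias = FALSE)
  set.seed(33)
  x <- random_tiny_inputs()
  tr <- forward_trace(net, x)
  rz <- lrp_backward(tr, 1, rule_config("z"))
  diffs <- sapply(10^-(2:6), function(e) {
    re <- lrp_backward(tr, 1, rule_config("epsilon", epsilon = e))
    max(abs(re$relevance$markers - rz$relevance$markers))
  })
  expect_true(all(diff(diffs) < 0))
  expect_lt(diffs[length(diffs)], 1e-5)
})

test_that("z-rule relevance is scale-equivariant for bias-free ReLU nets", {
  net <- tiny_quads(bias = FALSE)
  set.seed(41)
  x <- random_tiny_inputs()
  tr1 <- forward_trace(net, x)
  r1 <- lrp_backward(tr1, 0, rule_config("z"))
  tr2 <- forward_trace(net, lapply(x, function(m) 3 * m))
  r2 <- lrp_backward(tr2, 0, rule_config("z"))
  # logit scales by 3, and so does every relevance entry
  expect_equal(tr2$logits, 3 * tr1$logits, tolerance = 1e-10)
  expect_equal(r2$relevance$markers, 3 * r1$relevance$markers,
               tolerance = 1e-8)
})

test_that("composite and flat rules run and conserve the flat total", {
  net <- tiny_quads(bias = FALSE)
  set.seed(47)
  x <- random_tiny_inputs()
  tr <- forward_trace(net, x)
  for (rule in c("flat", "preset_a_flat")) {
    r <- lrp_backward(tr, 0, rule_config(rule))
    expect_true(all(vapply(r$relevance, function(m) all(is.finite(m)),
                           logical(1))))
  }
  expect_error(rule_config("alpha_beta", alpha = 3, beta = 1), "alpha - beta")
})

test_that("attention models are rejected by the tracer", {
  net <- build_model(model_spec(
    "transformer", "markers",
    list(shapes = list(markers = c(16L, 3L)), d_model = 4L, n_heads = 2L,
         d_ff = 6L, n_blocks = 1L, dropout = 0, head = 4L)), seed = 1)
  expect_error(forward_trace(net, list(markers = matrix(0, 16, 3))),
               "unsupported architecture")
})

test_that("gradient maps agree with central finite differences", {
  net <- tiny_quads(bias = TRUE)
  set.seed(53)
  x <- random_tiny_inputs()
  g <- baseline_analyzer(net, x, "gradient", target_class = 2)
  h <- 1e-5
  for (k in 1:10) {
    i <- sample(length(x$markers), 1)
    xp <- x; xp$markers[i] <- xp$markers[i] + h
    xm <- x; xm$markers[i] <- xm$markers[i] - h
    fd <- (forward_trace(net, xp)$logits[3] -
             forward_trace(net, xm)$logits[3]) / (2 * h)
    expect_equal(g$relevance$markers[i], fd, tolerance = 1e-4)
  }
})

test_that("saliency baselines honour their ReLU conventions", {
  net <- tiny_quads(bias = FALSE)
  set.seed(59)
  x <- random_tiny_inputs()
  inp <- baseline_analyzer(net, x, "input")
  expect_equal(inp$relevance$markers, x$markers)
  # a linear model's gradient map is its weight vector
  w <- matrix(c(0.5, -2, 3), 3, 1)
  lnet <- linear_net(w)
  gl <- baseline_analyzer(lnet, list(markers = matrix(rnorm(3), 3, 1)),
                          "gradient", target_class = 0)
  expect_equal(as.vector(gl$relevance$markers), as.vector(w))
  # an input pushing every ReLU into saturation-at-zero yields a zero
  # guided-backprop map
  zero_in <- lapply(random_tiny_inputs(), function(m) m * 0)
  gz <- baseline_analyzer(net, zero_in, "guided_backprop", target_class = 0)
  expect_true(all(gz$relevance$markers == 0))
})
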