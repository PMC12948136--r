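test_that("tiling covers the grid and orders tiles by heat", {
  # 585 x 156 grid under a 7 x 7 window: ceil(585/7) * ceil(156/7) tiles
  r <- matrix(0, 585, 156)
  ord <- morf_order(r, c(7L, 7L))
  expect_equal(nrow(ord$tiles), 84L * 23L)
  # concentrated relevance puts its tile first
  r2 <- matrix(0, 20, 20)
  r2[9:10, 15] <- 5
  o2 <- morf_order(r2, c(7L, 7L))
  expect_equal(o2$tiles$t0[1], 8L)
  expect_equal(o2$tiles$c0[1], 15L)
  # uniform relevance: ties resolve in (time, channel) order
  o3 <- morf_order(matrix(1, 14, 14), c(7L, 7L))
  expect_equal(o3$tiles$t0, c(1L, 1L, 8L, 8L))
  expect_equal(o3$tiles$c0, c(1L, 8L, 1L, 8L))
  expect_error(morf_order(matrix(0, 5, 10), c(7L, 7L)), "larger than")
  # channel span clamps for narrow modalities
  o4 <- morf_order(matrix(0, 30, 8), c(7L, 20L))
  expect_equal(o4$window[2], 8L)
})

test_that("tile perturbation is seeded, bounded and local", {
  x <- matrix(seq(-1, 1, length.out = 60), 20, 3)
  ord <- morf_order(matrix(runif(60), 20, 3), c(5L, 1L))
  b <- gaitxai:::channel_ranges(x)
  set.seed(77)
  x1 <- perturb_step(x, ord$tiles[1, ], b)
  set.seed(77)
  x2 <- perturb_step(x, ord$tiles[1, ], b)
  expect_identical(x1, x2)
  tile <- ord$tiles[1, ]
  inside <- matrix(FALSE, 20, 3)
  inside[tile$t0:tile$t1, tile$c0:tile$c1] <- TRUE
  expect_true(all(x1[!inside] == x[!inside]))
  expect_true(all(x1[inside] >= b$min[col(x)[inside]] &
                    x1[inside] <= b$max[col(x)[inside]]))
  # a window covering everything leaves no original value
  whole <- morf_order(matrix(1, 4, 2), c(4L, 2L))
  set.seed(1)
  xw <- perturb_step(matrix(5, 4, 2), whole$tiles[1, ],
                     list(min = c(0, 0), max = c(1, 1)))
  expect_true(all(xw != 5))
})

test_that("the MoRF curve starts unperturbed and a constant model gives AOPC 0", {
  # all-zero weights: logits are constant regardless of perturbation
  net <- linear_net(matrix(0, 6, 1))
  x <- list(markers = matrix(rnorm(6), 6, 1))
  ord <- morf_order(matrix(runif(6), 6, 1), c(2L, 1L))
  cur <- morf_curve(net, x, "markers", ord, L = 3, target_class = 0, seed = 4)
  expect_equal(cur$f[1], 0)         # f(x_MoRF(0)) = f(x)
  expect_equal(cur$drops, rep(0, 4))
  expect_equal(aopc(cur), 0)
  # L = 0: single term, zero drop
  cur0 <- morf_curve(net, x, "markers", ord, L = 0, target_class = 0)
  expect_equal(aopc(cur0), 0)
  expect_warning(morf_curve(net, x, "markers", ord, L = 99, target_class = 0),
                 "truncated")
})

test_that("pipeline AOPC equals brute-force evaluation on a 3-tile toy", {
  # linear model f = w'x over 3 one-frame tiles
  w <- matrix(c(2, -1, 0.5), 3, 1)
  net <- linear_net(w)
  x0 <- matrix(c(1, 2, 3), 3, 1)
  rel <- w * x0  # exact relevance of a linear model
  ord <- morf_order(matrix(rel, 3, 1), c(1L, 1L))
  seed <- 91
  cur <- morf_curve(net, list(markers = x0), "markers", ord, L = 3,
                    target_class = 0, seed = seed)
  # brute force: replay the same perturbation recursion by hand and
  # evaluate Eq-style drops directly
  b <- gaitxai:::channel_ranges(x0)
  xk <- x0
  f <- numeric(4)
  f[1] <- sum(w * xk)
  gaitxai:::with_seed(seed, {
    for (k in 1:3) {
      xk <- perturb_step(xk, ord$tiles[k, ], b)
      f[k + 1] <- sum(w * xk)
    }
  })
  expect_equal(cur$f, f, tolerance = 1e-12)
  expect_equal(aopc(cur), sum(f[1] - f) / 4, tolerance = 1e-12)
})

test_that("exactly linear drops integrate to AOPC = d * L / 2", {
  # constant input with degenerate replacement bounds [v, v]: every
  # perturbed frame deterministically moves from a to v, so the drop
  # after k steps is exactly k * (a - v) * span
  a <- 2; v <- 0.5
  T <- 8
  net <- linear_net(matrix(1, T, 1))     # f = sum of the frames
  x0 <- matrix(a, T, 1)
  ord <- morf_order(matrix(runif(T), T, 1), c(1L, 1L))
  b <- list(min = v, max = v)
  xk <- x0
  f <- numeric(T + 1)
  f[1] <- sum(xk)
  for (k in seq_len(T)) {
    xk <- perturb_step(xk, ord$tiles[k, ], b)
    f[k + 1] <- sum(xk)
  }
  drops <- f[1] - f
  d <- a - v
  expect_equal(drops, d * 0:T, tolerance = 1e-12)
  L <- T
  expect_equal(sum(drops) / (L + 1), d * L / 2, tolerance = 1e-12)
})

test_that("AOPC is invariant to constant logit shifts", {
  w <- matrix(c(1, -2, 0.3, 1.2), 4, 1)
  x <- list(markers = matrix(rnorm(4), 4, 1))
  ord <- morf_order(matrix(runif(4), 4, 1), c(1L, 1L))
  net_a <- linear_net(w)
  net_b <- linear_net(w, b = 10)         # same weights, shifted logit
  ca <- morf_curve(net_a, x, "markers", ord, L = 4, target_class = 0,
                   seed = 5)
  cb <- morf_curve(net_b, x, "markers", ord, L = 4, target_class = 0,
                   seed = 5)
  expect_equal(ca$drops, cb$drops, tolerance = 1e-10)
  expect_equal(aopc(ca), aopc(cb), tolerance = 1e-10)
})

test_that("analyzer comparison pairs noise streams and ranks identical analyzers equally", {
  net <- tiny_quads(bias = FALSE)
  set.seed(63)
  samples <- replicate(3, random_tiny_inputs(), simplify = FALSE)
  y <- vapply(samples, function(s) {
    which.max(forward_trace(net, s)$logits) - 1L
  }, integer(1))
  cmp <- compare_analyzers(net, samples, y,
                           list(a = "lrp_epsilon", b = "lrp_epsilon",
                                rnd = "random"),
                           modality = "markers", window = c(5L, 3L), L = 5,
                           seed = 17)
  expect_equal(cmp$per_sample["a", ], cmp$per_sample["b", ])
  expect_equal(nrow(cmp$aopc), 3L)
  expect_equal(sort(unique(cmp$curves$step)), 0:5)
  expect_true(all(cmp$curves$accuracy >= 0 & cmp$curves$accuracy <= 1))
  expect_error(compare_analyzers(net, samples, y, list(a = "lrp_z")),
               "at least two")
})
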