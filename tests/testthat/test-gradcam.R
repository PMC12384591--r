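test_that("target-layer activations have the final-conv shape and follow the input", {
  net <- build_network(tiny_spec(), seed = 2)
  win <- matrix(rnorm(16 * 8), 16, 8)
  tl <- target_layer_forward(net, win)
  # final conv output: time halved once (before the second pooling)
  expect_identical(dim(tl$activations), c(8L, 8L, 4L))
  expect_length(tl$logits, 2L)

  tl2 <- target_layer_forward(net, win)
  expect_identical(tl$activations, tl2$activations)

  # bias-free network maps zero input to zero activations (batch norm at its
  # untrained running statistics is a pure scaling)
  expect_true(all(target_layer_forward(net, matrix(0, 16, 8))$activations == 0))
})

test_that("logit gradients match central finite differences", {
  net <- build_network(tiny_spec(n_classes = 2), seed = 4)
  win <- matrix(rnorm(16 * 8), 16, 8)
  g <- class_gradients(net, win, 2)
  acts <- target_layer_forward(net, win)$activations
  expect_identical(dim(g), dim(acts))
  for (i in fd_safe_coords(acts, 20)) {
    eps <- 1e-5 * max(1, abs(acts[i]))
    ap <- acts; ap[i] <- acts[i] + eps
    am <- acts; am[i] <- acts[i] - eps
    fd <- (logits_from_activations(net, ap)[2] -
           logits_from_activations(net, am)[2]) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-3)
  }
  expect_error(class_gradients(net, win, 5), "class index")
})

test_that("a head that ignores a feature map gets an exactly zero gradient slice", {
  net <- build_network(tiny_spec(), seed = 6)
  K <- dim(target_layer_forward(net, matrix(0, 16, 8))$activations)[3]
  # zero every fc1 weight reading from feature map K of the flattened input
  flat_per_map <- net$layers$fc1$nin / K
  rows_k <- (K - 1) * flat_per_map + seq_len(flat_per_map)
  net$layers$fc1$W[rows_k, ] <- 0
  g <- class_gradients(net, matrix(rnorm(16 * 8), 16, 8), 1)
  expect_true(all(g[, , K] == 0))
  expect_true(any(g[, , 1] != 0))
})

test_that("gradient pooling and map weighting follow the stated arithmetic", {
  g <- array(1, dim = c(2, 2, 3))
  expect_equal(pool_gradients(g), c(1, 1, 1))
  g[, , 2] <- matrix(c(1, 3, 2, 4), 2, 2)   # mean 2.5
  g[, , 3] <- 0
  expect_equal(pool_gradients(g), c(1, 2.5, 0))

  a <- array(0, dim = c(1, 2, 1)); a[1, , 1] <- c(-1, 2)
  expect_equal(weighted_map(1, a), matrix(c(0, 2), 1, 2))
  a2 <- array(c(3, 5), dim = c(1, 1, 2))
  expect_equal(weighted_map(c(1, -1), a2), matrix(0, 1, 1))   # 3 - 5 clamped
  expect_equal(weighted_map(c(0, 0), a2), matrix(0, 1, 1))
  expect_error(weighted_map(c(1, 2, 3), a2), "does not match K")
})

test_that("bilinear upsampling matches an independent oracle and preserves constants", {
  const <- matrix(0.7, 64, 32)
  up <- upsample_to_input(const)
  expect_identical(dim(up), c(128L, 32L))
  expect_true(all(abs(up - 0.7) < 1e-12))

  two <- matrix(c(1, 3), 2, 1)
  expect_equal(upsample_to_input(two, c(4, 1)), bilinear_oracle(two, 4, 1))

  set.seed(9)
  m <- matrix(runif(8 * 5), 8, 5)
  expect_equal(upsample_to_input(m, c(16, 10)), bilinear_oracle(m, 16, 10),
               tolerance = 1e-12)
  expect_true(all(upsample_to_input(m, c(128, 32)) >= 0))
})

test_that("Grad-CAM reduces to CAM for a global-average-pooling head", {
  model <- gap_head_model(n_classes = 3, K = 5)
  win <- matrix(rnorm(12 * 6), 12, 6)
  tl <- target_layer_forward(model, win)
  for (cls in 1:3) {
    g <- class_gradients(model, win, cls)
    m <- weighted_map(pool_gradients(g), tl$activations)
    d <- dim(tl$activations)
    cam <- matrix(matrix(tl$activations, d[1] * d[2], d[3]) %*%
                    model$layers$head$W[, cls], d[1], d[2])
    cam[cam < 0] <- 0
    # equal up to the positive 1/Z factor
    if (max(cam) > 0) {
      expect_equal(m / max(m), cam / max(cam), tolerance = 1e-6)
    } else {
      expect_true(all(m == 0))
    }
  }
})

test_that("heatmaps are non-negative, input-shaped, and class-sensitive", {
  net <- build_network(tiny_spec(), seed = 12)
  w <- tiny_windows(3, seed = 14)
  m <- gradcam(net, windows_subset(w, 1), class = "true")
  expect_identical(dim(m), c(16L, 8L))
  expect_true(all(m >= 0))
  m2 <- gradcam(net, windows_subset(w, 1), class = 2)
  expect_false(isTRUE(all.equal(m, m2, check.attributes = FALSE)))
})

test_that("scaling a class's head weights rescales the map but not the scores", {
  net <- build_network(tiny_spec(n_classes = 2, keep = 1), seed = 15)
  win <- matrix(rnorm(16 * 8), 16, 8)
  scaled <- net
  scaled$layers$fc2$W[, 1] <- 3.7 * scaled$layers$fc2$W[, 1]
  m1 <- gradcam(net, win, class = 1)
  m2 <- gradcam(scaled, win, class = 1)
  expect_equal(3.7 * m1, m2, tolerance = 1e-9, ignore_attr = TRUE)
  v1 <- normalize_contribution(channel_means(m1))
  v2 <- normalize_contribution(channel_means(m2))
  expect_equal(v1$scores, v2$scores, tolerance = 1e-9)
})
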