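test_that("the canonical spec reproduces the documented layer shapes", {
  sh <- layer_shapes(network_spec(n_classes = 4))
  expect_equal(sh$out_time[sh$layer %in% c("conv1", "conv2", "conv3")], c(128, 128, 128))
  expect_equal(sh$out_time[sh$layer == "pool1"], 64)
  expect_equal(sh$out_time[sh$layer %in% c("conv4", "conv5", "conv6")], c(64, 64, 64))
  expect_equal(sh$out_time[sh$layer == "pool2"], 32)
  expect_true(all(sh$out_width[!is.na(sh$out_width)] == 32))
  expect_equal(sh$units[sh$layer == "flatten"], 131072)
  expect_equal(sh$units[sh$layer == "fc1"], 512)
  expect_equal(sh$units[sh$layer == "fc2"], 4)
  expect_equal(sh$units[sh$layer %in% paste0("conv", 1:6)],
               c(32, 32, 64, 64, 64, 128))
})

test_that("spec validation rejects inconsistent configurations", {
  expect_error(network_spec(conv_filters = c(8, 8, 8)), "six")
  expect_error(network_spec(n_classes = 3), "2 or 4")
  expect_error(network_spec(kernel = c(4, 4)), "odd")
  expect_error(network_spec(dropout_keep = 0), "dropout_keep")
})

test_that("the learning rate halves every half-life", {
  s <- network_spec()
  expect_equal(lr_schedule(0, s), 1e-3)
  expect_equal(lr_schedule(49, s), 1e-3)
  expect_equal(lr_schedule(50, s), 5e-4)
  expect_equal(lr_schedule(100, s), 2.5e-4)
})

test_that("prediction is a proper softmax, stateless and batch-size invariant", {
  spec <- tiny_spec()
  net <- build_network(spec, seed = 3)
  w <- tiny_windows(12, seed = 7)
  pr <- predict(net, w)
  expect_equal(rowSums(pr$prob), rep(1, 12), tolerance = 1e-9)

  # duplicated window -> identical probability rows
  w2 <- windows_subset(w, c(1, 1, 2))
  pr2 <- predict(net, w2)
  expect_identical(pr2$prob[1, ], pr2$prob[2, ])

  # batch of 1 vs one big batch
  one <- predict(net, windows_subset(w, 5), batch = 1)
  expect_equal(one$prob[1, ], pr$prob[5, ], tolerance = 1e-12)

  # zeroed output layer -> uniform probabilities
  net0 <- net
  net0$layers$fc2$W[] <- 0
  net0$layers$fc2$b[] <- 0
  pr0 <- predict(net0, w)
  expect_equal(unname(pr0$prob), matrix(0.5, 12, 2), tolerance = 1e-12)

  expect_error(predict(net, tiny_windows(2, n_ch = 4, len = 16)), "shape")
})

test_that("training is deterministic under a fixed seed and reduces the loss", {
  w <- tiny_windows(40, seed = 11)
  # plant a trivial difference so there is something to learn
  w$data[1, , w$label == "HA"] <- w$data[1, , w$label == "HA"] + 2
  spec <- tiny_spec(epochs = 6)
  m1 <- fit_cnn(w, spec = spec, seed = 5)
  m2 <- fit_cnn(w, spec = spec, seed = 5)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_identical(m1$layers$fc2$W, m2$layers$fc2$W)
  expect_lt(m1$history$loss[6], m1$history$loss[1])
})

test_that("stronger L2 decay shrinks the weights at equal seed", {
  w <- tiny_windows(40, seed = 12)
  sumsq <- function(m) sum(vapply(m$layers, function(l)
    if (!is.null(l$W)) sum(l$W^2) else 0, numeric(1)))
  m_free <- fit_cnn(w, spec = tiny_spec(epochs = 5, l2_coeff = 0), seed = 2)
  m_l2 <- fit_cnn(w, spec = tiny_spec(epochs = 5, l2_coeff = 10), seed = 2)
  expect_lt(sumsq(m_l2), sumsq(m_free))
})

test_that("removing the residual links changes the computed function", {
  spec <- tiny_spec()
  net <- build_network(spec, seed = 9)
  cut <- net
  cut$layers$res1_add$P[] <- 0
  cut$layers$res2_add$P[] <- 0
  w <- tiny_windows(4, seed = 13)
  expect_false(isTRUE(all.equal(predict(net, w)$prob, predict(cut, w)$prob)))
  # and the ablated spec drops them entirely
  noskip <- build_network(tiny_spec(residual = FALSE), seed = 9)
  expect_false("res1_add" %in% names(noskip$layers))
})

test_that("parameter gradients agree with finite differences on a tiny net", {
  spec <- tiny_spec(keep = 1)  # dropout off so the loss is deterministic
  net <- build_network(spec, seed = 21)
  w <- tiny_windows(6, seed = 22)
  x <- eegcam:::windows_to_tensor(w)
  y <- as.integer(w$label)
  loss_of <- function(layers) {
    out <- eegcam:::net_forward(layers, x, training = TRUE)$out
    p <- eegcam:::softmax_cols(out)
    -mean(log(p[cbind(y, seq_along(y))]))
  }
  fw <- eegcam:::net_forward(net$layers, x, training = TRUE)
  p <- eegcam:::softmax_cols(fw$out)
  g <- p; g[cbind(y, seq_along(y))] <- g[cbind(y, seq_along(y))] - 1
  bw <- eegcam:::net_backward(net$layers, fw$caches, g / length(y))

  checks <- list(c("conv2", "W"), c("conv5", "b"), c("res1_add", "P"),
                 c("conv4_bn", "gamma"), c("fc1_bn", "beta"), c("fc2", "W"))
  set.seed(30)
  for (ck in checks) {
    li <- which(names(net$layers) == ck[1])
    par <- net$layers[[li]][[ck[2]]]
    i <- sample(length(par), 1)
    eps <- 1e-5
    lp <- net$layers; lp[[li]][[ck[2]]][i] <- par[i] + eps
    lm <- net$layers; lm[[li]][[ck[2]]][i] <- par[i] - eps
    fd <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
    an <- bw$pgrads[[li]][[ck[2]]][i]
    expect_equal(an, fd, tolerance = 1e-5,
                 label = paste("gradient of", ck[1], ck[2]))
  }
})
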