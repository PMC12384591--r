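#' CNN architecture and training hyperparameters
#'
#' Describes the 2D CNN: six 5x5 same-padded convolutions over the
#' (time x electrode) window, two (2,1) max-poolings (after the 3rd and 6th
#' convolutions) that halve only the temporal axis, residual links from the
#' 1st to the 3rd and from the 4th to the 6th convolution (1x1 projection on
#' the skip when filter counts differ), one 512-unit fully connected layer
#' and an N-logit output. Regularization: structured (whole-feature-map)
#' dropout with retention 0.5 after conv 1/3/4/6 and fc1, batch norm after
#' conv 2/4/5 and fc1, L2 weight decay in the loss, and a learning-rate
#' schedule that halves the rate every `lr_half_life` epochs.
#'
#' The canonical configuration (the defaults) gives temporal dimensions
#' 128 -> 64 -> 32 and a flatten length of 32*32*128 = 131,072.
#'
#' @param n_classes number of output classes (2 or 4).
#' @param conv_filters six filter counts, default `c(32, 32, 64, 64, 64, 128)`.
#' @param kernel convolution kernel, default `c(5, 5)` (odd sizes only).
#' @param fc1_units width of the first fully connected layer (default 512).
#' @param input_shape `(time, channels)` of one window, default `c(128, 32)`.
#' @param dropout_keep retention probability in `(0, 1]` (default 0.5).
#' @param l2_coeff L2 weight-decay strength (loss adds `l2_coeff * sum(W^2)`).
#' @param lr0 initial learning rate (default 1e-3, Adam).
#' @param lr_half_life epochs between 50% learning-rate cuts (default 50).
#' @param batch_size minibatch size (default 240).
#' @param epochs default number of training epochs.
#' @param residual keep the two residual links (`TRUE`; `FALSE` ablates them).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(n_classes = 4L,
                         conv_filters = c(32L, 32L, 64L, 64L, 64L, 128L),
                         kernel = c(5L, 5L),
                         fc1_units = 512L,
                         input_shape = c(128L, 32L),
                         dropout_keep = 0.5,
                         l2_coeff = 1e-4,
                         lr0 = 1e-3,
                         lr_half_life = 50L,
                         batch_size = 240L,
                         epochs = 200L,
                         residual = TRUE) {
  if (length(conv_filters) != 6L) stop("conv_filters must list six filter counts")
  if (!(n_classes %in% c(2L, 4L))) stop("n_classes must be 2 or 4")
  if (any(kernel %% 2 == 0)) stop("kernel sizes must be odd (same padding)")
  if (dropout_keep <= 0 || dropout_keep > 1) stop("dropout_keep must be in (0, 1]")
  if (input_shape[1] %% 4 != 0) stop("temporal length must be divisible by 4 (two (2,1) poolings)")
  structure(list(n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel),
                 fc1_units = as.integer(fc1_units),
                 input_shape = as.integer(input_shape),
                 dropout_keep = dropout_keep,
                 l2_coeff = l2_coeff, lr0 = lr0,
                 lr_half_life = as.integer(lr_half_life),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 residual = isTRUE(residual)),
            class = "network_spec")
}

#' Learning-rate schedule
#'
#' `lr0 * 0.5 ^ floor(epoch / lr_half_life)`: the rate is cut by 50% every
#' `lr_half_life` epochs (epoch counted from 0).
#'
#' @param epoch epoch index >= 0.
#' @param spec a [network_spec()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, spec) {
  stopifnot(epoch >= 0)
  spec$lr0 * 0.5^(epoch %/% spec$lr_half_life)
}

#' Per-layer output shapes of a network spec
#'
#' @param spec a [network_spec()].
#' @return data.frame with columns `layer`, `out_time`, `out_width`, `units`
#'   (filter count for convolutions, vector length for flatten/dense rows,
#'   where spatial rows carry NA units and dense rows carry NA shapes).
#' @export
layer_shapes <- function(spec) {
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  f <- spec$conv_filters
  rows <- list(
    c("input", H, W, NA),
    c("conv1", H, W, f[1]), c("conv2", H, W, f[2]), c("conv3", H, W, f[3]),
    c("pool1", H / 2, W, f[3]),
    c("conv4", H / 2, W, f[4]), c("conv5", H / 2, W, f[5]), c("conv6", H / 2, W, f[6]),
    c("pool2", H / 4, W, f[6]),
    c("flatten", NA, NA, H / 4 * W * f[6]),
    c("fc1", NA, NA, spec$fc1_units),
    c("fc2", NA, NA, spec$n_classes))
  data.frame(layer = vapply(rows, `[`, "", 1),
             out_time = as.numeric(vapply(rows, `[`, "", 2)),
             out_width = as.numeric(vapply(rows, `[`, "", 3)),
             units = as.numeric(vapply(rows, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

assemble_layers <- function(spec) {
  k <- spec$kernel; f <- spec$conv_filters; keep <- spec$dropout_keep
  H <- spec$input_shape[1]; W <- spec$input_shape[2]
  L <- list()
  add <- function(l) L[[length(L) + 1L]] <<- l
  add(layer_conv("conv1", k[1], k[2], 1L, f[1]))
  add(layer_relu("conv1_act")); add(layer_dropout("conv1_drop", keep))
  if (spec$residual) add(layer_tap("res1_tap", "r1"))
  add(layer_conv("conv2", k[1], k[2], f[1], f[2]))
  add(layer_bn("conv2_bn", f[2])); add(layer_relu("conv2_act"))
  add(layer_conv("conv3", k[1], k[2], f[2], f[3]))
  if (spec$residual) add(layer_resadd("res1_add", "r1", f[1], f[3]))
  add(layer_relu("conv3_act")); add(layer_dropout("conv3_drop", keep))
  add(layer_pool("pool1"))
  add(layer_conv("conv4", k[1], k[2], f[3], f[4]))
  add(layer_bn("conv4_bn", f[4])); add(layer_relu("conv4_act"))
  add(layer_dropout("conv4_drop", keep))
  if (spec$residual) add(layer_tap("res2_tap", "r2"))
  add(layer_conv("conv5", k[1], k[2], f[4], f[5]))
  add(layer_bn("conv5_bn", f[5])); add(layer_relu("conv5_act"))
  add(layer_conv("conv6", k[1], k[2], f[5], f[6]))
  if (spec$residual) add(layer_resadd("res2_add", "r2", f[4], f[6]))
  add(layer_relu("conv6_act"))  # Grad-CAM target: final conv, post-activation
  add(layer_dropout("conv6_drop", keep))
  add(layer_pool("pool2"))
  add(layer_flatten("flatten"))
  add(layer_dense("fc1", (H / 4) * W * f[6], spec$fc1_units))
  add(layer_bn("fc1_bn", spec$fc1_units, kind = "dense"))
  add(layer_relu("fc1_act")); add(layer_dropout("fc1_drop", keep, spatial = FALSE))
  add(layer_dense("fc2", spec$fc1_units, spec$n_classes))
  L
}

#' Build the CNN from a spec
#'
#' Instantiates the layer stack with fan-in-scaled random initial weights and
#' computes the per-layer shape report.
#'
#' @param spec a [network_spec()].
#' @param seed RNG seed for weight initialization.
#' @param class_levels optional character vector of class labels (length
#'   `n_classes`) carried along for prediction.
#' @return object of class `eeg_cnn`: layers, spec, shape report, the index
#'   of the Grad-CAM target layer, and (after [fit_cnn()]) a training history.
#' @export
build_network <- function(spec = network_spec(), seed = 1L, class_levels = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  layers <- lapply(assemble_layers(spec), init_layer_params)
  names(layers) <- vapply(layers, `[[`, "", "name")
  target <- which(names(layers) == "conv6_act")
  if (is.null(class_levels)) class_levels <- paste0("class", seq_len(spec$n_classes))
  structure(list(layers = layers, spec = spec, shape_report = layer_shapes(spec),
                 target_index = target, class_levels = class_levels,
                 rng_seed = seed, history = NULL),
            class = "eeg_cnn")
}

windows_to_tensor <- function(w) {
  d <- dim(w$data)  # (C, L, n)
  x <- aperm(w$data, c(2, 1, 3))  # (L=time, C=electrode, n)
  dim(x) <- c(d[2], d[1], 1L, d[3])
  x
}

collect_params <- function(layers) {
  out <- list()
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    for (p in intersect(names(l), c("W", "b", "P", "gamma", "beta"))) {
      if (!is.null(l[[p]])) out[[paste0(li, ".", p)]] <- l[[p]]
    }
  }
  out
}

#' Train the CNN
#'
#' Minimizes softmax cross-entropy plus `l2_coeff * sum(W^2)` over all
#' convolution, projection and dense weights with the Adam optimizer,
#' structured dropout, batch norm (running statistics tracked for inference)
#' and the halving learning-rate schedule. Deterministic under a fixed seed.
#'
#' @param windows an `eeg_windows` set (labels must match the spec's
#'   `n_classes`).
#' @param spec a [network_spec()]; or pass a pre-built `net`.
#' @param epochs number of epochs (default `spec$epochs`).
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @param net optional pre-built [build_network()] object to continue from.
#' @param verbose print per-epoch progress.
#' @return a fitted `eeg_cnn` with `history` (epoch, lr, loss, accuracy on
#'   the training windows).
#' @export
fit_cnn <- function(windows, spec = network_spec(n_classes = length(levels(windows$label))),
                    epochs = NULL, seed = 1L, net = NULL, verbose = FALSE) {
  stopifnot(inherits(windows, "eeg_windows"))
  if (is.null(net)) net <- build_network(spec, seed = seed,
                                         class_levels = levels(windows$label))
  spec <- net$spec
  if (is.null(epochs)) epochs <- spec$epochs
  y <- as.integer(windows$label)
  if (anyNA(y)) stop("windows carry labels outside the scheme")
  if (length(y) == 0L) stop("empty window set")
  if (max(y) > spec$n_classes) stop("label index exceeds n_classes")
  x_all <- windows_to_tensor(windows)
  n <- dim(x_all)[4]
  set.seed(seed + 1L)

  layers <- net$layers
  adam_m <- list(); adam_v <- list(); tstep <- 0
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     loss = numeric(), accuracy = numeric())

  for (ep in seq_len(epochs) - 1L) {
    lr <- lr_schedule(ep, spec)
    ord <- sample.int(n)
    bs <- min(spec$batch_size, n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      xb <- x_all[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- net_forward(layers, xb, training = TRUE)
      logits <- fw$out
      p <- softmax_cols(logits)
      B <- length(yb)
      ce <- -mean(log(pmax(p[cbind(yb, seq_len(B))], 1e-12)))
      ep_loss <- ep_loss + ce * B
      ep_correct <- ep_correct + sum(max.col(t(p)) == yb)
      g <- p
      g[cbind(yb, seq_len(B))] <- g[cbind(yb, seq_len(B))] - 1
      g <- g / B
      bw <- net_backward(layers, fw$caches, g)
      tstep <- tstep + 1
      for (li in seq_along(layers)) {
        l <- layers[[li]]
        if (l$type == "bn") layers[[li]] <- bn_update_running(l, fw$caches[[li]])
        pg <- bw$pgrads[[li]]
        if (is.null(pg)) next
        for (pn in names(pg)) {
          gr <- pg[[pn]]
          if (pn %in% c("W", "P")) gr <- gr + 2 * spec$l2_coeff * layers[[li]][[pn]]
          key <- paste0(li, ".", pn)
          if (is.null(adam_m[[key]])) { adam_m[[key]] <- gr * 0; adam_v[[key]] <- gr * 0 }
          adam_m[[key]] <- b1 * adam_m[[key]] + (1 - b1) * gr
          adam_v[[key]] <- b2 * adam_v[[key]] + (1 - b2) * gr^2
          mhat <- adam_m[[key]] / (1 - b1^tstep)
          vhat <- adam_v[[key]] / (1 - b2^tstep)
          layers[[li]][[pn]] <- layers[[li]][[pn]] - lr * mhat / (sqrt(vhat) + aeps)
        }
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, lr = lr, loss = ep_loss / n,
                                   accuracy = ep_correct / n))
    if (verbose) message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f",
                                 ep, lr, ep_loss / n, ep_correct / n))
  }
  net$layers <- layers
  net$history <- hist
  net
}

#' Predict class probabilities and labels for windows
#'
#' Runs the network in inference mode (dropout disabled, batch norm on its
#' running statistics), so predictions are deterministic and batch-size
#' invariant.
#'
#' @param object a fitted `eeg_cnn`.
#' @param windows an `eeg_windows` set (or a bare time x electrode matrix).
#' @param batch maximum forward batch size.
#' @param ... unused.
#' @return list with `prob` (n x n_classes matrix, rows summing to 1) and
#'   `label` (factor of argmax classes).
#' @export
predict.eeg_cnn <- function(object, windows, batch = 240L, ...) {
  x <- if (inherits(windows, "eeg_windows")) windows_to_tensor(windows)
       else if (is.matrix(windows)) array(windows, dim = c(dim(windows), 1L, 1L))
       else stop("windows must be an eeg_windows set or a time x electrode matrix")
  exp_hw <- object$spec$input_shape
  if (!all(dim(x)[1:2] == exp_hw))
    stop("window shape ", dim(x)[1], " x ", dim(x)[2],
         " does not match the spec input ", exp_hw[1], " x ", exp_hw[2])
  n <- dim(x)[4]
  probs <- matrix(0, n, object$spec$n_classes)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- net_forward(object$layers, x[, , , idx, drop = FALSE], training = FALSE)
    probs[idx, ] <- t(softmax_cols(fw$out))
  }
  colnames(probs) <- object$class_levels
  list(prob = probs,
       label = factor(object$class_levels[max.col(probs, ties.method = "first")],
                      levels = object$class_levels))
}

#' Classification accuracy on a window set
#' @param model a fitted `eeg_cnn`.
#' @param windows an `eeg_windows` set.
#' @return accuracy in percent.
#' @export
accuracy <- function(model, windows) {
  pr <- predict(model, windows)
  100 * mean(as.character(pr$label) == as.character(windows$label))
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat("2D CNN for EEG windows (", x$spec$input_shape[1], "x",
      x$spec$input_shape[2], "), ", x$spec$n_classes, " classes\n", sep = "")
  cat("  filters:", paste(x$spec$conv_filters, collapse = "-"),
      " fc1:", x$spec$fc1_units,
      " residual:", x$spec$residual, "\n")
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, train accuracy %.1f%%\n",
                nrow(x$history), last$loss, 100 * last$accuracy))
  } else cat("  untrained (random initialization)\n")
  invisible(x)
}

#' @export
summary.eeg_cnn <- function(object, ...) {
  print(object)
  cat("\nLayer shapes:\n")
  print(object$shape_report, row.names = FALSE)
  invisible(object$shape_report)
}

#' @export
plot.eeg_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot")
  graphics::par(mfrow = c(1, 2))
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  graphics::plot(x$history$epoch, 100 * x$history$accuracy, type = "l",
                 xlab = "epoch", ylab = "training accuracy (%)", ...)
  invisible(x)
}
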