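#' Target-layer activations and logits for one window
#'
#' Runs the network in inference mode and returns the activations of the
#' Grad-CAM target layer — the final convolutional layer, taken after its
#' activation and before the second max-pooling (H x W x K; 64 x 32 x 128 for
#' the canonical spec) — together with the pre-softmax logit vector.
#'
#' @param model an `eeg_cnn`.
#' @param window a time x electrode matrix matching the spec input (or an
#'   `eeg_windows` set of size 1).
#' @return list with `activations` (H x W x K array) and `logits`.
#' @export
target_layer_forward <- function(model, window) {
  x <- single_window_tensor(model, window)
  fw <- net_forward(model$layers, x, training = FALSE,
                    record_at = model$target_index)
  a <- fw$recorded
  dim(a) <- dim(a)[1:3]
  list(activations = a, logits = as.vector(fw$out))
}

single_window_tensor <- function(model, window) {
  if (inherits(window, "eeg_windows")) {
    if (n_windows(window) != 1L) stop("pass a single window")
    x <- windows_to_tensor(window)
  } else if (is.matrix(window)) {
    x <- array(window, dim = c(dim(window), 1L, 1L))
  } else stop("window must be a matrix or a single-window eeg_windows")
  exp_hw <- model$spec$input_shape
  if (!all(dim(x)[1:2] == exp_hw))
    stop("window shape does not match the network input ",
         exp_hw[1], " x ", exp_hw[2])
  x
}

#' Logits from given target-layer activations
#'
#' Runs only the head of the network (the layers after the Grad-CAM target)
#' on externally supplied activations. This is the function differentiated by
#' [class_gradients()]; exposing it lets the gradient be checked against
#' finite differences.
#'
#' @param model an `eeg_cnn`.
#' @param acts H x W x K activation array (the target layer's output shape).
#' @return numeric vector of `n_classes` logits.
#' @export
logits_from_activations <- function(model, acts) {
  a <- acts
  dim(a) <- c(dim(acts)[1:3], 1L)
  fw <- net_forward(model$layers, a, training = FALSE,
                    start_at = model$target_index + 1L)
  as.vector(fw$out)
}

#' Gradient of a class logit with respect to the target-layer activations
#'
#' Exact reverse-mode gradient of the pre-softmax logit for class `c` (never
#' the softmax probability) with respect to the final convolutional layer's
#' activations, with the network in inference mode.
#'
#' @param model an `eeg_cnn`.
#' @param window time x electrode matrix.
#' @param class class index in `1..n_classes`.
#' @return H x W x K array of gradients.
#' @export
class_gradients <- function(model, window, class) {
  class <- as.integer(class)
  if (class < 1L || class > model$spec$n_classes) stop("invalid class index")
  x <- single_window_tensor(model, window)
  fw <- net_forward(model$layers, x, training = FALSE)
  gout <- matrix(0, model$spec$n_classes, 1L)
  gout[class, 1L] <- 1
  bw <- net_backward(model$layers, fw$caches, gout, wrt = model$target_index)
  g <- bw$g_at
  dim(g) <- dim(g)[1:3]
  g
}

#' Global-average-pool the gradients into per-feature-map weights
#'
#' `alpha_k = (1/Z) * sum_ij grad[i, j, k]` with `Z = H * W`.
#'
#' @param grads H x W x K gradient array from [class_gradients()].
#' @return numeric vector of K weights.
#' @export
pool_gradients <- function(grads) {
  d <- dim(grads)
  colMeans(matrix(grads, d[1] * d[2], d[3]))
}

#' Weighted, rectified combination of feature maps
#'
#' `ReLU(sum_k alpha_k * A^k)`: the per-map weights multiply the activations,
#' the maps are summed, and negative entries are clamped to zero so only
#' positive class evidence remains.
#'
#' @param weights vector of K per-map weights.
#' @param acts H x W x K activation array.
#' @return H x W non-negative matrix.
#' @export
weighted_map <- function(weights, acts) {
  d <- dim(acts)
  if (length(weights) != d[3])
    stop("weights length ", length(weights), " does not match K = ", d[3])
  m <- matrix(matrix(acts, d[1] * d[2], d[3]) %*% weights, d[1], d[2])
  m[m < 0] <- 0
  m
}

#' Bilinear upsampling to the input grid
#'
#' Upsamples an H x W map to the network input size (128 x 32 by default)
#' with bilinear interpolation on half-pixel centers without corner
#' alignment: output pixel i samples source coordinate
#' `(i + 0.5) * H_in / H_out - 0.5`, clamped to the source range. Constant
#' maps stay constant and non-negativity is preserved.
#'
#' @param map H x W matrix.
#' @param out_shape target `(rows, cols)`, default `c(128, 32)`.
#' @return `out_shape[1]` x `out_shape[2]` matrix.
#' @export
upsample_to_input <- function(map, out_shape = c(128L, 32L)) {
  interp_axis <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    frac <- src - lo
    list(lo = as.integer(lo) + 1L, hi = pmin(as.integer(lo) + 2L, n_in), w = frac)
  }
  ri <- interp_axis(nrow(map), out_shape[1])
  ci <- interp_axis(ncol(map), out_shape[2])
  rows <- map[ri$lo, , drop = FALSE] * (1 - ri$w) + map[ri$hi, , drop = FALSE] * ri$w
  sweep(rows[, ci$lo, drop = FALSE], 2, 1 - ci$w, `*`) +
    sweep(rows[, ci$hi, drop = FALSE], 2, ci$w, `*`)
}

#' Grad-CAM heatmap for one window
#'
#' Composition of the gradient, pooling, weighting and upsampling steps: a
#' non-negative class-conditional heatmap on the input grid
#' (time x electrode), localizing where the evidence for the class lies.
#'
#' @param model an `eeg_cnn`.
#' @param window time x electrode matrix (or single-window `eeg_windows`).
#' @param class `"true"` is not available for a bare matrix; pass an integer
#'   class index, `"predicted"`, or (for an `eeg_windows` input) `"true"`.
#' @return 128 x 32 non-negative matrix with attribute `class_index`.
#' @export
gradcam <- function(model, window, class = "predicted") {
  if (identical(class, "true")) {
    if (!inherits(window, "eeg_windows")) stop("'true' class needs an eeg_windows input")
    class <- as.integer(window$label[1L])
  } else if (identical(class, "predicted")) {
    class <- as.integer(predict(model, window)$label[1L])
  }
  tl <- target_layer_forward(model, window)
  g <- class_gradients(model, window, class)
  m <- upsample_to_input(weighted_map(pool_gradients(g), tl$activations),
                         model$spec$input_shape)
  attr(m, "class_index") <- class
  m
}

# Batched Grad-CAM channel means. One inference forward plus one truncated
# backward per batch: the per-sample logit gradients are independent at
# inference, so a one-hot matrix over the batch yields every sample's
# gradient in a single reverse pass.
gradcam_batch_channel_means <- function(model, windows,
                                        class = c("true", "predicted"),
                                        batch = 240L) {
  if (!is.numeric(class)) class <- match.arg(class)
  x_all <- windows_to_tensor(windows)
  n <- dim(x_all)[4]
  W_in <- model$spec$input_shape[2]
  out <- matrix(0, n, W_in)
  cls_used <- integer(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    xb <- x_all[, , , idx, drop = FALSE]
    fw <- net_forward(model$layers, xb, training = FALSE,
                      record_at = model$target_index)
    B <- length(idx)
    cls <- if (is.numeric(class)) rep(as.integer(class), B)
           else if (class == "true") as.integer(windows$label[idx])
           else max.col(t(fw$out), ties.method = "first")
    gout <- matrix(0, model$spec$n_classes, B)
    gout[cbind(cls, seq_len(B))] <- 1
    bw <- net_backward(model$layers, fw$caches, gout, wrt = model$target_index)
    grads <- bw$g_at
    acts <- fw$recorded
    d <- dim(acts)  # (H, W, K, B)
    hw <- d[1] * d[2]
    for (bi in seq_len(B)) {
      a_b <- matrix(acts[, , , bi], hw, d[3])
      alpha <- colMeans(matrix(grads[, , , bi], hw, d[3]))
      m <- matrix(a_b %*% alpha, d[1], d[2])
      m[m < 0] <- 0
      up <- upsample_to_input(m, model$spec$input_shape)
      out[idx[bi], ] <- colMeans(up)
    }
    cls_used[idx] <- cls
  }
  attr(out, "class_used") <- cls_used
  out
}
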