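# Shared helpers and independent oracles for the test suite.

# round-half-up to d decimals, matching how summary tables are printed
# (R's round() is round-half-even)
round_half_up <- function(x, d = 2) floor(x * 10^d + 0.5) / 10^d

# a small window set with random data and given labels, for exercising the
# network machinery without full-size trials
tiny_windows <- function(n, n_ch = 8L, len = 16L, levels = c("LA", "HA"),
                         labels = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep_len(levels, n)
  structure(list(
    data = array(rnorm(n_ch * len * n), dim = c(n_ch, len, n)),
    label = factor(labels, levels = levels),
    trial_id = sprintf("t%03d", rep(seq_len(max(1, n %/% 4)), length.out = n)),
    subject_id = rep("s01", n),
    window_index = seq_len(n) - 1L,
    scheme = list(task = "test", threshold = 5, levels = levels)),
    class = "eeg_windows")
}

tiny_spec <- function(n_classes = 2L, filters = c(2L, 2L, 3L, 3L, 3L, 4L),
                      input_shape = c(16L, 8L), fc1 = 8L, keep = 0.5,
                      batch = 20L, ...) {
  network_spec(n_classes = n_classes, conv_filters = filters,
               input_shape = input_shape, fc1_units = fc1,
               dropout_keep = keep, batch_size = batch, ...)
}

# a minimal CAM-compatible model: conv -> ReLU (Grad-CAM target) -> global
# average pooling -> linear head; exercises the same forward/backward engine
gap_head_model <- function(n_classes = 3L, K = 5L, input_shape = c(12L, 6L),
                           seed = 42L) {
  set.seed(seed)
  layers <- list(
    eegcam:::layer_conv("conv1", 3L, 3L, 1L, K),
    eegcam:::layer_relu("conv1_act"),
    eegcam:::layer_gap("gap"),
    eegcam:::layer_dense("head", K, n_classes))
  layers <- lapply(layers, eegcam:::init_layer_params)
  names(layers) <- vapply(layers, `[[`, "", "name")
  layers$head$b <- rnorm(n_classes)
  structure(list(layers = layers,
                 spec = list(n_classes = n_classes, input_shape = input_shape),
                 target_index = 2L,
                 class_levels = paste0("c", seq_len(n_classes)),
                 history = NULL),
            class = "eeg_cnn")
}

# Coordinates of `acts` (H x W x K) that are safe for a finite-difference
# gradient check through the downstream (2,1) max-pooling: skip positions
# whose pooling partner is within `margin`, where the pooled max is a kink
# and one-sided derivatives differ.
fd_safe_coords <- function(acts, n = 20, margin = 1e-2, seed = 5) {
  d <- dim(acts)
  ridx <- arrayInd(seq_along(acts), d)
  partner_row <- ridx[, 1] + ifelse(ridx[, 1] %% 2 == 1, 1L, -1L)
  partner <- cbind(partner_row, ridx[, 2], ridx[, 3])
  ok <- abs(acts[seq_along(acts)] - acts[partner]) > margin
  set.seed(seed)
  sample(which(ok), n)
}

# independently coded bilinear interpolation (half-pixel centers, clamped),
# scalar loops only — the oracle for upsample_to_input()
bilinear_oracle <- function(map, out_rows, out_cols) {
  out <- matrix(0, out_rows, out_cols)
  for (i in seq_len(out_rows)) {
    for (j in seq_len(out_cols)) {
      sy <- min(max((i - 0.5) * nrow(map) / out_rows - 0.5, 0), nrow(map) - 1)
      sx <- min(max((j - 0.5) * ncol(map) / out_cols - 0.5, 0), ncol(map) - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, nrow(map) - 1); x1 <- min(x0 + 1, ncol(map) - 1)
      fy <- sy - y0; fx <- sx - x0
      out[i, j] <-
        map[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        map[y1 + 1, x0 + 1] * fy * (1 - fx) +
        map[y0 + 1, x1 + 1] * (1 - fy) * fx +
        map[y1 + 1, x1 + 1] * fy * fx
    }
  }
  out
}

# quadrant LDA accuracy on trial-level planted-band power: the independent
# (non-CNN) route for checking the planted effect's separability
lda_bandpower_accuracy <- function(effect, seed, n_per_class = 20,
                                   channels = c(20L, 22L),
                                   segment = "stimulus") {
  ds <- generate_dataset(plant_spec(effect_size = effect, seed = seed),
                         n_per_class)
  lab <- vapply(ds$trials,
                function(t) as.character(label_trial(t, label_scheme("quaternary"))),
                "")
  feat <- t(vapply(ds$trials,
                   function(t) as.vector(band_power(t, c(10, 20),
                                                    channels = channels,
                                                    segment = segment)),
                   numeric(2 * length(channels))))
  idx <- seq(1, length(lab), by = 2)
  fit <- MASS::lda(feat[idx, ], grouping = lab[idx])
  mean(predict(fit, feat[-idx, ])$class == lab[-idx])
}
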