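#' Per-channel means of a Grad-CAM heatmap
#'
#' Collapses a 128 x 32 (time x electrode) heatmap to one importance value
#' per EEG channel by averaging over the time axis.
#'
#' @param map 128 x 32 heatmap matrix (time in rows, electrodes in columns).
#' @return numeric vector of length 32.
#' @export
channel_means <- function(map) {
  if (!is.matrix(map)) stop("map must be a matrix")
  colMeans(map)
}

#' Per-sample Grad-CAM channel means for a window set
#'
#' Computes one Grad-CAM heatmap per window (for its true or predicted
#' class) and reduces each to its 32 per-channel time means. This is the
#' sample-level matrix that the aggregation, normalization and stability
#' analyses consume.
#'
#' @param model a fitted `eeg_cnn`.
#' @param windows an `eeg_windows` set.
#' @param class `"true"` (default; heatmaps for each window's label),
#'   `"predicted"`, or a fixed integer class index.
#' @param batch forward/backward batch size.
#' @return n x 32 matrix with attribute `class_used`.
#' @export
contribution_samples <- function(model, windows, class = "true", batch = 240L) {
  gradcam_batch_channel_means(model, windows, class = class, batch = batch)
}

#' Average per-sample channel vectors by class
#'
#' @param samples n x C matrix of per-sample channel means.
#' @param labels optional factor/vector of length n; when supplied, one mean
#'   vector per class is returned (a class with zero samples is an error),
#'   otherwise a single pooled mean vector.
#' @return a C-vector (pooled) or classes x C matrix of raw mean scores.
#' @export
aggregate_contributions <- function(samples, labels = NULL) {
  if (is.null(labels)) return(colMeans(samples))
  labels <- as.factor(labels)
  if (any(table(labels) == 0L))
    stop("class with zero samples: ",
         paste(levels(labels)[table(labels) == 0L], collapse = ", "))
  out <- t(vapply(levels(labels),
                  function(lv) colMeans(samples[labels == lv, , drop = FALSE]),
                  numeric(ncol(samples))))
  rownames(out) <- levels(labels)
  out
}

#' Min-max normalize raw channel scores to a 0-1 contribution vector
#'
#' `(x - min) / (max - min)`, so the least important channel maps to 0 and
#' the most important to 1. A constant input has no spread to normalize; it
#' maps to all zeros and is flagged degenerate rather than raising an error.
#' The scaling is invariant under positive affine transforms of the input,
#' which makes the scores invariant to the arbitrary overall scale of the
#' Grad-CAM maps.
#'
#' @param raw numeric vector of raw per-channel scores.
#' @param task optional task/class tag carried in the result.
#' @param n_samples_used optional sample count carried in the result.
#' @return object of class `contribution_vector`: `scores` in `[0, 1]`,
#'   `task`, `n_samples_used`, `degenerate` flag.
#' @export
normalize_contribution <- function(raw, task = NULL, n_samples_used = NA_integer_) {
  rng <- range(raw)
  degenerate <- !(rng[2] > rng[1])
  scores <- if (degenerate) rep(0, length(raw)) else (raw - rng[1]) / (rng[2] - rng[1])
  structure(list(scores = scores, task = task,
                 n_samples_used = n_samples_used, degenerate = degenerate),
            class = "contribution_vector")
}

#' @export
print.contribution_vector <- function(x, ...) {
  cat("Normalized contribution scores")
  if (!is.null(x$task)) cat(" (", x$task, ")", sep = "")
  cat(if (x$degenerate) " [degenerate: constant input]\n" else "\n")
  print(round(x$scores, 3))
  invisible(x)
}

#' @export
plot.contribution_vector <- function(x, names = NULL, threshold = NULL, ...) {
  nm <- if (is.null(names)) seq_along(x$scores) else names
  bp <- graphics::barplot(x$scores, names.arg = nm, las = 2,
                          ylab = "Normalized Contribution Score", ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(bp)
}

#' Task-level contribution scores from a fitted model
#'
#' End-to-end convenience: per-window Grad-CAM channel means, aggregated
#' (pooled across samples, or per class) and min-max normalized.
#'
#' @inheritParams contribution_samples
#' @param per_class return one normalized vector per class instead of a
#'   single pooled vector.
#' @return a `contribution_vector`, or a named list of them if `per_class`.
#' @export
contribution_scores <- function(model, windows, class = "true",
                                per_class = FALSE, batch = 240L) {
  samples <- contribution_samples(model, windows, class = class, batch = batch)
  if (!per_class) {
    return(normalize_contribution(aggregate_contributions(samples),
                                  task = windows$scheme$task,
                                  n_samples_used = nrow(samples)))
  }
  agg <- aggregate_contributions(samples, windows$label)
  out <- lapply(rownames(agg), function(lv)
    normalize_contribution(agg[lv, ], task = lv,
                           n_samples_used = sum(windows$label == lv)))
  names(out) <- rownames(agg)
  out
}

#' Select high-contribution channels by threshold
#'
#' Channels whose normalized score strictly exceeds the threshold, reported
#' as electrode names in montage order. Defaults follow the per-task choices
#' of the contribution analysis: 0.6 for the binary arousal task, 0.5
#' otherwise.
#'
#' @param vector a `contribution_vector` (or bare numeric vector).
#' @param threshold selection cut in `[0, 1]`; `NULL` picks the per-task
#'   default.
#' @param montage electrode names in channel order.
#' @return object of class `channel_subset`: `channels` (names), `index`,
#'   `threshold`, `task`.
#' @export
select_channels <- function(vector, threshold = NULL, montage = montage_names()) {
  task <- NULL
  if (inherits(vector, "contribution_vector")) {
    task <- vector$task
    vector <- vector$scores
  }
  if (is.null(threshold)) threshold <- if (identical(task, "arousal")) 0.6 else 0.5
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (length(montage) != length(vector)) stop("montage/vector length mismatch")
  keep <- which(vector > threshold)
  structure(list(channels = montage[keep], index = keep,
                 threshold = threshold, task = task),
            class = "channel_subset")
}

#' @export
print.channel_subset <- function(x, ...) {
  cat(sprintf("%d channels above %.2f%s: %s\n", length(x$channels), x$threshold,
              if (is.null(x$task)) "" else paste0(" (", x$task, ")"),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Pearson correlation between two channel vectors
#'
#' @param v1,v2 equal-length numeric vectors (length >= 2, nonzero variance).
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_r <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal length")
  if (length(v1) < 2L) stop("need at least two values")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) stop("zero-variance input")
  stats::cor(v1, v2, method = "pearson")
}

#' Subset-stability analysis of the contribution scores
#'
#' Draws random subsets (without replacement) of the per-sample channel
#' vectors, recomputes the pooled normalized contribution vector and the
#' selected channel set on each subset, and reports the Pearson correlation
#' against the full-data vector. A final row at the full sample size is
#' included; its correlation is 1 by construction.
#'
#' @param samples n x 32 matrix from [contribution_samples()].
#' @param sizes subset sizes (each <= n), strictly increasing.
#' @param seed RNG seed for the draws.
#' @param threshold selection cut passed to [select_channels()].
#' @param montage electrode names.
#' @param task optional task tag.
#' @return object of class `stability_report`: data.frame `table` with
#'   columns `subset_size`, `channels` (comma-joined names), `pcc`, plus the
#'   per-size subsets and the full-data `contribution_vector`.
#' @export
subset_stability <- function(samples, sizes, seed = 1L, threshold = 0.5,
                             montage = montage_names(), task = NULL) {
  n <- nrow(samples)
  sizes <- as.integer(sizes)
  if (any(sizes > n)) stop("subset size exceeds available samples (", n, ")")
  if (is.unsorted(sizes, strictly = TRUE)) stop("sizes must be strictly increasing")
  full_vec <- normalize_contribution(aggregate_contributions(samples), task = task,
                                     n_samples_used = n)
  set.seed(seed)
  all_sizes <- c(sizes, n)
  rows <- vector("list", length(all_sizes))
  subsets <- vector("list", length(all_sizes))
  for (i in seq_along(all_sizes)) {
    s <- all_sizes[i]
    idx <- if (s == n) seq_len(n) else sample.int(n, s)
    v <- normalize_contribution(aggregate_contributions(samples[idx, , drop = FALSE]),
                                task = task, n_samples_used = s)
    sel <- select_channels(v, threshold = threshold, montage = montage)
    rows[[i]] <- data.frame(subset_size = s,
                            channels = paste(sel$channels, collapse = ", "),
                            pcc = pearson_r(v$scores, full_vec$scores),
                            stringsAsFactors = FALSE)
    subsets[[i]] <- sel
  }
  structure(list(table = do.call(rbind, rows), subsets = subsets,
                 full = full_vec, threshold = threshold, seed = seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Channel-contribution stability (threshold ", x$threshold, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
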