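#' Seed-deterministic k-fold split
#'
#' Shuffles the windows and partitions them into k folds whose sizes differ
#' by at most one. With `group_by`, whole trials (or subjects) are assigned
#' to folds together, preventing windows of one recording from straddling
#' the train/test boundary.
#'
#' @param windows an `eeg_windows` set (or an integer count).
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @param group_by `"none"` (pooled windows, the default protocol),
#'   `"trial"`, or `"subject"`.
#' @return integer vector of fold ids (1..k), one per window.
#' @export
kfold_split <- function(windows, k = 10L, seed = 1L,
                        group_by = c("none", "trial", "subject")) {
  group_by <- match.arg(group_by)
  n <- if (inherits(windows, "eeg_windows")) n_windows(windows) else as.integer(windows)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("too few windows (", n, ") for ", k, " folds")
  set.seed(seed)
  if (group_by == "none") {
    folds <- integer(n)
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
    return(folds)
  }
  key <- if (group_by == "trial")
    paste(windows$subject_id, windows$trial_id) else windows$subject_id
  groups <- unique(key)
  if (length(groups) < k) stop("too few ", group_by, " groups for ", k, " folds")
  # stratified by class: deal each class's groups round-robin onto the folds
  # so grouped folds stay class-balanced
  gclass <- as.character(windows$label[match(groups, key)])
  gf <- integer(length(groups))
  offset <- 0L
  for (cl in unique(gclass)) {
    gi <- which(gclass == cl)
    gf[gi[sample.int(length(gi))]] <- (offset + seq_along(gi) - 1L) %% k + 1L
    offset <- offset + length(gi)
  }
  gf[match(key, groups)]
}

#' Mean and population standard deviation of fold accuracies
#'
#' The summary convention is the population (divide-by-n) standard
#' deviation, not the sample (divide-by-n-1) one; both values are kept at
#' full precision and rounded only for display.
#'
#' @param acc numeric vector of fold accuracies (>= 1 value).
#' @return list with `mean` and `sd` (population).
#' @export
aggregate_report <- function(acc) {
  if (length(acc) == 0L) stop("no fold accuracies to aggregate")
  m <- mean(acc)
  list(mean = m, sd = sqrt(mean((acc - m)^2)))
}

#' k-fold cross-validation of the CNN
#'
#' Trains a fresh network on k-1 folds and evaluates window-level top-1
#' accuracy (%) on the held-out fold, for each fold in turn; aggregates the
#' per-fold accuracies into their mean and population standard deviation.
#'
#' @param windows an `eeg_windows` set.
#' @param spec a [network_spec()].
#' @param k number of folds (default 10).
#' @param seed RNG seed (fold split and per-fold training seeds derive from
#'   it).
#' @param epochs epochs per fold (default `spec$epochs`).
#' @param group_by fold granularity, see [kfold_split()]. The default pools
#'   windows across trials; note that windows of one trial then appear on
#'   both sides of the split, so use `"trial"` for a leakage-free protocol.
#' @param verbose print per-fold progress.
#' @return object of class `cv_report`: `folds` data.frame (fold, accuracy,
#'   n_train, n_test), `mean`, `sd` (population), `task`, `k`, `seed`.
#' @export
cross_validate <- function(windows, spec, k = 10L, seed = 1L, epochs = NULL,
                           group_by = "none", verbose = FALSE) {
  folds <- kfold_split(windows, k = k, seed = seed, group_by = group_by)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- windows_subset(windows, which(folds != f))
    te <- windows_subset(windows, which(folds == f))
    model <- fit_cnn(tr, spec = spec, epochs = epochs, seed = seed + f)
    acc <- accuracy(model, te)
    rows[[f]] <- data.frame(fold = f, accuracy = acc,
                            n_train = n_windows(tr), n_test = n_windows(te))
    if (verbose) message(sprintf("fold %d/%d: %.2f%%", f, k, acc))
  }
  tab <- do.call(rbind, rows)
  agg <- aggregate_report(tab$accuracy)
  structure(list(folds = tab, mean = agg$mean, sd = agg$sd,
                 task = windows$scheme$task, k = k, seed = seed,
                 group_by = group_by),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, task '%s' (%s folds)\n",
              x$k, x$task,
              if (x$group_by == "none") "pooled-window" else paste0("by-", x$group_by)))
  print(x$folds, row.names = FALSE)
  cat(sprintf("Mean %.2f  Std.Dev (population) %.2f\n", x$mean, x$sd))
  invisible(x)
}

#' @export
plot.cv_report <- function(x, ...) {
  graphics::barplot(x$folds$accuracy, names.arg = x$folds$fold,
                    xlab = "fold", ylab = "accuracy (%)", ...)
  graphics::abline(h = x$mean, lty = 2)
  invisible(x)
}

#' End-to-end synthetic benchmark
#'
#' Chains the whole pipeline at desk scale on synthetic data with known
#' planted channels: generate a balanced quadrant dataset, preprocess into
#' baseline-corrected windows, train the (scaled-down) CNN, compute Grad-CAM
#' contribution scores, select channels, and run the subset-stability
#' analysis on an independently generated evaluation set.
#'
#' @param seed master seed for generation, training and stability draws.
#' @param effect_size planted effect multiplier (default 2).
#' @param windows_per_class training windows kept per class (default 200).
#' @param epochs training epochs (default 30).
#' @param filters,fc1_units scaled-down architecture (defaults
#'   `c(2, 2, 4, 4, 4, 8)` and 32; the full-scale defaults of
#'   [network_spec()] are impractical on a laptop-class CPU).
#' @param planted planted channel indices (1-based; default F4/FC6 positions).
#' @param n_eval_per_class evaluation trials per class for the attribution
#'   and stability stages (default 5, i.e. 1200 windows).
#' @param stability_sizes subset sizes for [subset_stability()].
#' @param holdout_frac fraction of training windows held out for test
#'   accuracy.
#' @return list with the fitted `model`, `train_accuracy` and `test_accuracy`
#'   (%, on held-out windows of the training trials), `transfer_accuracy`
#'   (%, on the independently generated evaluation trials — a leakage-free
#'   generalization measure), pooled `scores` (`contribution_vector`),
#'   `selected` (`channel_subset`), `stability` (`stability_report`), and
#'   `planted`.
#' @export
synthetic_benchmark <- function(seed = 1L, effect_size = 2,
                                windows_per_class = 200L, epochs = 30L,
                                filters = c(2L, 2L, 4L, 4L, 4L, 8L),
                                fc1_units = 32L,
                                planted = c(20L, 22L),
                                n_eval_per_class = 5L,
                                stability_sizes = c(100L, 500L, 1000L),
                                holdout_frac = 0.25) {
  plant <- plant_spec(planted_channels = planted, effect_size = effect_size,
                      seed = seed)
  n_per_class <- ceiling(windows_per_class / 60)
  ds <- generate_dataset(plant, n_per_class = n_per_class)
  w <- preprocess_trials(ds, label_scheme("quaternary"))
  set.seed(seed)
  keep <- unlist(lapply(levels(w$label), function(lv) {
    pool <- which(w$label == lv)
    sort(sample(pool, min(windows_per_class, length(pool))))
  }))
  w <- windows_subset(w, keep)
  n <- n_windows(w)
  te_idx <- sort(sample.int(n, round(holdout_frac * n)))
  tr <- windows_subset(w, setdiff(seq_len(n), te_idx))
  te <- windows_subset(w, te_idx)

  spec <- network_spec(n_classes = 4L, conv_filters = filters,
                       fc1_units = fc1_units, batch_size = 120L,
                       epochs = epochs)
  model <- fit_cnn(tr, spec = spec, seed = seed)

  eval_plant <- plant_spec(planted_channels = planted, effect_size = effect_size,
                           seed = seed + 10000L)
  ev <- preprocess_trials(generate_dataset(eval_plant, n_eval_per_class),
                          label_scheme("quaternary"))
  samples <- contribution_samples(model, ev, class = "true")
  scores <- normalize_contribution(aggregate_contributions(samples),
                                   task = "quaternary",
                                   n_samples_used = nrow(samples))
  selected <- select_channels(scores, threshold = 0.5)
  stab <- subset_stability(samples, sizes = stability_sizes, seed = seed,
                           threshold = 0.5, task = "quaternary")
  list(model = model,
       train_accuracy = accuracy(model, tr),
       test_accuracy = accuracy(model, te),
       transfer_accuracy = accuracy(model, ev),
       scores = scores, selected = selected, stability = stab,
       planted = planted, n_train = n_windows(tr), n_test = n_windows(te),
       n_eval = n_windows(ev))
}
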