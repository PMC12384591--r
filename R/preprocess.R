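#' Baseline mean template
#'
#' Segments the pre-stimulus baseline (C x B) into `B / seg_len` consecutive
#' C x L blocks and averages them element-wise into a single C x L template.
#' For the DEAP layout (B = 384, L = 128) this averages N = 3 segments.
#'
#' @param baseline numeric matrix, channels x baseline samples.
#' @param seg_len segment length L (default 128).
#' @return list of class `baseline_template` with `template` (C x L matrix)
#'   and `n_segments_used`.
#' @export
baseline_template <- function(baseline, seg_len = 128L) {
  if (!is.matrix(baseline)) stop("baseline must be a matrix")
  B <- ncol(baseline); seg_len <- as.integer(seg_len)
  if (B %% seg_len != 0L)
    stop("baseline length ", B, " is not divisible by segment length ", seg_len)
  n_seg <- B %/% seg_len
  tmpl <- matrix(0, nrow(baseline), seg_len)
  for (s in seq_len(n_seg)) {
    tmpl <- tmpl + baseline[, ((s - 1L) * seg_len + 1L):(s * seg_len), drop = FALSE]
  }
  structure(list(template = tmpl / n_seg, n_segments_used = n_seg),
            class = "baseline_template")
}

#' Subtract the baseline template from stimulus data
#'
#' Slices the stimulus matrix (C x T, T divisible by L) into consecutive
#' C x L blocks and subtracts the template from each block; the shape is
#' preserved.
#'
#' @param stimulus numeric matrix, channels x samples.
#' @param template a [baseline_template()] (or bare C x L matrix).
#' @return corrected matrix of the same shape as `stimulus`.
#' @export
remove_baseline <- function(stimulus, template) {
  if (inherits(template, "baseline_template")) template <- template$template
  if (!is.matrix(stimulus) || !is.matrix(template)) stop("matrix inputs required")
  if (nrow(stimulus) != nrow(template))
    stop("channel-count mismatch: ", nrow(stimulus), " vs ", nrow(template))
  L <- ncol(template); T_ <- ncol(stimulus)
  if (T_ %% L != 0L)
    stop("stimulus length ", T_, " is not divisible by template length ", L)
  out <- stimulus
  for (k in seq_len(T_ %/% L)) {
    idx <- ((k - 1L) * L + 1L):(k * L)
    out[, idx] <- stimulus[, idx, drop = FALSE] - template
  }
  out
}

#' Cut a trial into baseline-corrected, labeled windows
#'
#' Computes the baseline template from the trial's baseline region, subtracts
#' it from the stimulus region, slices the result into non-overlapping C x L
#' windows in temporal order, and attaches the trial's class label (from its
#' ratings) to every window. A DEAP-shaped 32 x 8064 trial with 384 baseline
#' samples yields exactly 60 windows of 32 x 128.
#'
#' @param trial an [eeg_trial()].
#' @param scheme a [label_scheme()].
#' @param seg_len window length L (default 128).
#' @return an `eeg_windows` object: list with `data` (array C x L x n),
#'   `label` (factor, one per window), `trial_id`, `subject_id`,
#'   `window_index`, and the `scheme`.
#' @export
make_windows <- function(trial, scheme = label_scheme(), seg_len = 128L) {
  stopifnot(inherits(trial, "eeg_trial"))
  nb <- trial$n_baseline
  tmpl <- baseline_template(trial$data[, seq_len(nb), drop = FALSE], seg_len)
  stim <- remove_baseline(trial$data[, (nb + 1L):ncol(trial$data), drop = FALSE], tmpl)
  L <- as.integer(seg_len); n_win <- ncol(stim) %/% L
  dat <- array(stim, dim = c(nrow(stim), L, n_win))  # col-major: consecutive blocks
  lab <- label_trial(trial, scheme)
  structure(list(data = dat,
                 label = factor(rep(as.character(lab), n_win), levels = scheme$levels),
                 trial_id = rep(trial$trial_id, n_win),
                 subject_id = rep(trial$subject_id, n_win),
                 window_index = seq_len(n_win) - 1L,
                 scheme = scheme),
            class = "eeg_windows")
}

#' Preprocess many trials into one window set
#'
#' Applies [make_windows()] to each trial and concatenates the results.
#'
#' @param trials an `eeg_dataset` or list of [eeg_trial()].
#' @param scheme a [label_scheme()].
#' @param seg_len window length L.
#' @return an `eeg_windows` object.
#' @export
preprocess_trials <- function(trials, scheme = label_scheme(), seg_len = 128L) {
  if (inherits(trials, "eeg_dataset")) trials <- trials$trials
  parts <- lapply(trials, make_windows, scheme = scheme, seg_len = seg_len)
  bind_windows(parts)
}

#' Combine window sets
#' @param parts list of `eeg_windows` objects sharing one scheme and shape.
#' @return a single `eeg_windows` object.
#' @export
bind_windows <- function(parts) {
  stopifnot(length(parts) >= 1L)
  d1 <- dim(parts[[1L]]$data)
  n <- sum(vapply(parts, function(p) dim(p$data)[3], integer(1)))
  dat <- array(0, dim = c(d1[1], d1[2], n))
  at <- 0L
  for (p in parts) {
    k <- dim(p$data)[3]
    dat[, , (at + 1L):(at + k)] <- p$data
    at <- at + k
  }
  structure(list(data = dat,
                 label = factor(unlist(lapply(parts, function(p) as.character(p$label))),
                                levels = parts[[1L]]$scheme$levels),
                 trial_id = unlist(lapply(parts, `[[`, "trial_id")),
                 subject_id = unlist(lapply(parts, `[[`, "subject_id")),
                 window_index = unlist(lapply(parts, `[[`, "window_index")),
                 scheme = parts[[1L]]$scheme),
            class = "eeg_windows")
}

#' Subset a window set
#' @param w an `eeg_windows` object.
#' @param idx window indices to keep.
#' @return an `eeg_windows` object.
#' @export
windows_subset <- function(w, idx) {
  structure(list(data = w$data[, , idx, drop = FALSE],
                 label = w$label[idx],
                 trial_id = w$trial_id[idx],
                 subject_id = w$subject_id[idx],
                 window_index = w$window_index[idx],
                 scheme = w$scheme),
            class = "eeg_windows")
}

#' @export
print.eeg_windows <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("%d windows of %d x %d, task '%s'\n", d[3], d[1], d[2], x$scheme$task))
  print(table(x$label))
  invisible(x)
}

#' Number of windows
#' @param w an `eeg_windows` object.
#' @return integer count.
#' @export
n_windows <- function(w) dim(w$data)[3]
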