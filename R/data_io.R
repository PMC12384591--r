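#' Construct an EEG trial
#'
#' One multichannel recording of shape channels x samples at 128 Hz whose
#' leading `n_baseline` samples are the pre-stimulus baseline, together with
#' the trial's self-reported arousal and valence ratings on the 1-9 scale.
#'
#' @param data numeric matrix, channels x samples.
#' @param n_baseline number of leading baseline samples (default 384 = 3 s).
#' @param arousal,valence ratings in `[1, 9]` (floats allowed).
#' @param subject_id,trial_id opaque identifier strings.
#' @return object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, n_baseline = 384L, arousal, valence,
                      subject_id = "s01", trial_id = "t01") {
  if (!is.matrix(data) || !is.numeric(data)) stop("data must be a numeric matrix")
  n_baseline <- as.integer(n_baseline)
  if (ncol(data) < n_baseline)
    stop("data has fewer columns (", ncol(data), ") than n_baseline (", n_baseline, ")")
  for (nm in c("arousal", "valence")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 1 || r > 9)
      stop(nm, " rating outside [1, 9]: ", r)
  }
  structure(list(data = data, n_baseline = n_baseline,
                 arousal = as.numeric(arousal), valence = as.numeric(valence),
                 subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id)),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("EEG trial %s/%s: %d x %d (%d baseline samples), arousal=%g valence=%g\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data),
              x$n_baseline, x$arousal, x$valence))
  invisible(x)
}

#' Rating-threshold labeling scheme
#'
#' Fixes the classification task and the rating threshold. Ratings <= 5 are
#' "low" and > 5 are "high" (strict inequality at the threshold), both for
#' the binary tasks and for the four arousal x valence quadrants.
#'
#' @param task `"arousal"`, `"valence"`, or `"quaternary"`.
#' @param threshold rating cut (default 5; low <= threshold < high).
#' @return object of class `label_scheme` with a `levels` field giving the
#'   ordered class labels (`LA/HA`, `LV/HV`, or `LALV/HALV/LAHV/HAHV`).
#' @export
label_scheme <- function(task = c("quaternary", "arousal", "valence"),
                         threshold = 5) {
  task <- match.arg(task)
  levels <- switch(task,
                   arousal = c("LA", "HA"),
                   valence = c("LV", "HV"),
                   quaternary = QUADRANTS)
  structure(list(task = task, threshold = threshold, levels = levels),
            class = "label_scheme")
}

#' Label a trial from its ratings
#'
#' @param trial an [eeg_trial()].
#' @param scheme a [label_scheme()].
#' @return a single factor level: `LA`/`HA`, `LV`/`HV`, or a quadrant label.
#' @export
label_trial <- function(trial, scheme = label_scheme()) {
  stopifnot(inherits(trial, "eeg_trial"), inherits(scheme, "label_scheme"))
  th <- scheme$threshold
  lab <- switch(scheme$task,
    arousal = if (trial$arousal > th) "HA" else "LA",
    valence = if (trial$valence > th) "HV" else "LV",
    quaternary = paste0(if (trial$arousal > th) "H" else "L", "A",
                        if (trial$valence > th) "H" else "L", "V"))
  factor(lab, levels = scheme$levels)
}

#' The packaged 32-electrode montage
#'
#' Electrode names of the 10-20 system in the channel order documented for
#' the preprocessed DEAP release. The ordering is configuration, not code: it
#' ships as a user-editable CSV under `inst/extdata/deap_montage.csv`.
#'
#' @param path optional path to an alternative montage CSV with columns
#'   `index,name` (index 1..32).
#' @return character vector of 32 unique electrode names, in channel order.
#' @export
montage_names <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "deap_montage.csv", package = "eegcam")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "name") %in% names(m))) stop("montage CSV needs index,name columns")
  m <- m[order(m$index), ]
  nm <- as.character(m$name)
  if (length(nm) != 32L || anyDuplicated(nm))
    stop("montage must list exactly 32 unique electrode names")
  nm
}

## ---- generic array containers (rds-based) -----------------------------------

#' Write / read an EEG dataset container
#'
#' The generic container is a single compressed `.rds` archive holding the
#' data arrays, ratings, baseline length and identifiers; `read_dataset()`
#' restores it bit-exactly.
#'
#' @param x an `eeg_dataset` or list of [eeg_trial()].
#' @param path file path (`.rds`).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns the restored object.
#' @export
write_dataset <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  readRDS(path)
}

#' Read a preprocessed-DEAP-layout subject container
#'
#' Reads one subject's container in the preprocessed-DEAP layout: a
#' 40 x 40 x 8064 data array (trials x channels x samples; only the first 32
#' channels, the EEG channels, are kept) plus a 40 x 4 ratings array whose
#' columns follow the DEAP labels convention (valence, arousal, dominance,
#' liking). Two on-disk forms are accepted:
#' \itemize{
#'   \item an `.rds` file holding `list(data = <40x40x8064>, labels = <40x4>)`;
#'   \item a directory with `eeg.bin` (float64 little-endian, written in
#'     C-order from a `(40, 40, 8064)` array, e.g. via `numpy.tofile`) and
#'     `ratings.csv` (40 rows, 4 numeric columns).
#' }
#'
#' @param path path to the container.
#' @return list of 40 [eeg_trial()] objects with `n_baseline = 384`.
#' @export
read_deap_subject <- function(path) {
  if (dir.exists(path)) {
    bin <- file.path(path, "eeg.bin")
    rat <- file.path(path, "ratings.csv")
    if (!file.exists(bin) || !file.exists(rat))
      stop("directory container needs eeg.bin and ratings.csv")
    raw <- readBin(bin, what = "double", n = 40 * 40 * 8064 + 1, size = 8,
                   endian = "little")
    if (length(raw) != 40 * 40 * 8064)
      stop("eeg.bin holds ", length(raw),
           " values; expected 40 x 40 x 8064 = ", 40 * 40 * 8064)
    # C-order (trial, channel, sample) -> R array (sample, channel, trial), then flip
    data <- aperm(array(raw, dim = c(8064, 40, 40)), c(3, 2, 1))
    labels <- as.matrix(utils::read.csv(rat, header = TRUE))
  } else {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$data) || is.null(obj$labels))
      stop("rds container must hold list(data=, labels=)")
    data <- obj$data; labels <- obj$labels
  }
  d <- dim(data)
  if (length(d) != 3L || d[1] != 40L)
    stop("trial dimension malformed: expected 40 trials, found ",
         if (length(d) == 3L) d[1] else "a non-3D array")
  if (d[2] < 32L) stop("channel dimension malformed: expected >= 32, found ", d[2])
  if (d[3] != 8064L) stop("sample dimension malformed: expected 8064, found ", d[3])
  if (!is.matrix(labels) || nrow(labels) != 40L || ncol(labels) < 2L)
    stop("ratings array malformed: expected 40 x 4")
  if (any(labels[, 1:2] < 1 | labels[, 1:2] > 9))
    stop("rating outside [1,9] in ratings array")
  lapply(seq_len(40L), function(i) {
    eeg_trial(matrix(data[i, 1:32, ], nrow = 32L),
              n_baseline = 384L,
              arousal = labels[i, 2], valence = labels[i, 1],
              subject_id = basename(path), trial_id = sprintf("t%02d", i))
  })
}

#' Write a DEAP-layout subject container (round-trip writer)
#'
#' Serializes a 40 x 40 x 8064 array and 40 x 4 ratings matrix in the `.rds`
#' container form accepted by [read_deap_subject()]. Mainly used to exercise
#' the reader without the gated original download.
#'
#' @param data 40 x 40 x 8064 array (trials x channels x samples).
#' @param labels 40 x 4 ratings matrix (valence, arousal, dominance, liking).
#' @param path output `.rds` path.
#' @export
write_deap_subject <- function(data, labels, path) {
  saveRDS(list(data = data, labels = labels), path)
  invisible(path)
}

## ---- contribution CSV -------------------------------------------------------

#' Write / read per-channel contribution scores as CSV
#'
#' One row per channel (`index`, `name`, then one numeric column per class or
#' task). Scores are formatted with 17 significant digits so a re-read is
#' bit-exact.
#'
#' @param scores numeric matrix 32 x n_classes (columns named by class), or a
#'   length-32 vector.
#' @param montage character vector of 32 electrode names.
#' @param path output CSV path.
#' @export
write_contributions <- function(scores, montage = montage_names(), path) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L,
                                             dimnames = list(NULL, "score"))
  if (nrow(scores) != 32L) stop("contribution vectors must have length 32")
  if (length(montage) != nrow(scores))
    stop("montage/vector length mismatch: ", length(montage), " vs ", nrow(scores))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("class", seq_len(ncol(scores)))
  num <- apply(scores, 2, function(col) sprintf("%.17g", col))
  tab <- cbind(index = seq_len(nrow(scores)), name = montage, num)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contributions
#' @export
read_contributions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  scores <- as.matrix(tab[, setdiff(names(tab), c("index", "name")), drop = FALSE])
  storage.mode(scores) <- "double"
  rownames(scores) <- tab$name
  scores
}
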