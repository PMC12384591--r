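#' Specification of a planted class effect for synthetic EEG
#'
#' Describes how class-discriminative signal is planted into synthetic trials:
#' which channels carry it, how strong it is relative to the noise floor, and
#' the seed from which every per-trial random substream is derived.
#'
#' The effect model is oscillatory band power, the canonical EEG feature: on
#' the planted channels the stimulus segment receives a ~10 Hz sinusoid whose
#' amplitude depends on the arousal level and a ~20 Hz sinusoid whose
#' amplitude depends on the valence level (low level: `0.5 * effect_size *
#' noise_sd`; high level: `1.5 * effect_size * noise_sd`), each with a random
#' phase per trial and channel. With `effect_size = 0` both levels collapse to
#' amplitude zero and the classes are statistically indistinguishable. A
#' per-channel DC offset (sd `baseline_offset_sd`) is shared by the baseline
#' and stimulus segments, so baseline subtraction is demonstrably useful.
#'
#' @param planted_channels integer vector of 1-based channel indices (subset
#'   of 1..32) that carry the class effect. Default `c(20, 22)`, the F4 and
#'   FC6 positions of the packaged montage.
#' @param effect_kind `"oscillation-power"` (the default effect model) or
#'   `"amplitude"` (a constant class-dependent shift instead of a sinusoid).
#' @param effect_size dimensionless multiplier >= 0 scaling the planted
#'   amplitudes relative to `noise_sd`.
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise floor
#'   (signal units), > 0.
#' @param baseline_offset_sd standard deviation of the per-channel DC offset
#'   shared by baseline and stimulus (signal units), >= 0.
#' @param seed integer master seed; it fans out deterministically to
#'   per-trial substreams so datasets are bit-reproducible.
#' @return An object of class `plant_spec`.
#' @seealso [generate_trial()], [generate_dataset()]
#' @export
plant_spec <- function(planted_channels = c(20L, 22L),
                       effect_kind = c("oscillation-power", "amplitude"),
                       effect_size = 2,
                       noise_sd = 1,
                       baseline_offset_sd = 1,
                       seed = 1L) {
  effect_kind <- match.arg(effect_kind)
  planted_channels <- as.integer(planted_channels)
  if (length(planted_channels) == 0L)
    stop("planted_channels must be non-empty")
  if (anyDuplicated(planted_channels))
    stop("planted_channels must be duplicate-free")
  if (any(planted_channels < 1L | planted_channels > 32L))
    stop("planted_channels must lie in 1..32")
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0)
    stop("effect_size must be a single number >= 0")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0)
    stop("noise_sd must be > 0")
  if (baseline_offset_sd < 0) stop("baseline_offset_sd must be >= 0")
  structure(list(planted_channels = planted_channels,
                 effect_kind = effect_kind,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

QUADRANTS <- c("LALV", "HALV", "LAHV", "HAHV")

# Deterministic per-trial substream seed derived from the master seed.
# Kept below 2^31 so it is always a valid R integer seed.
trial_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 7919) %% 2147480989)
}

#' Generate one synthetic DEAP-layout EEG trial
#'
#' Produces a 32 x 8064 trial at 128 Hz: 384 baseline samples (noise +
#' per-channel offset, never any class effect) followed by 7680 stimulus
#' samples (noise + the same offset + the planted class effect on
#' `plant$planted_channels` only). Ratings are drawn so that thresholding at
#' 5 (low <= 5 < high) reproduces `target_class` deterministically: low
#' ratings are uniform on \{1..5\}, high ratings uniform on \{6..9\}.
#'
#' @param plant a [plant_spec()].
#' @param target_class one of `"LALV"`, `"HALV"`, `"LAHV"`, `"HAHV"`.
#' @param stream integer substream index (>= 1); together with `plant$seed`
#'   it fixes the trial bit-exactly, independent of generation order.
#' @param subject_id,trial_id opaque identifier strings.
#' @return An [eeg_trial()] object.
#' @export
generate_trial <- function(plant, target_class, stream = 1L,
                           subject_id = "synthetic", trial_id = NULL) {
  stopifnot(inherits(plant, "plant_spec"))
  if (!is.character(target_class) || length(target_class) != 1L ||
      !(target_class %in% QUADRANTS))
    stop("target_class must be one of ", paste(QUADRANTS, collapse = ", "))
  n_ch <- 32L; n_base <- 384L; n_total <- 8064L; fs <- 128
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(trial_seed(plant$seed, stream))

  high_a <- target_class %in% c("HALV", "HAHV")
  high_v <- target_class %in% c("LAHV", "HAHV")
  arousal <- if (high_a) sample(6:9, 1L) else sample(1:5, 1L)
  valence <- if (high_v) sample(6:9, 1L) else sample(1:5, 1L)

  x <- matrix(stats::rnorm(n_ch * n_total, sd = plant$noise_sd), n_ch, n_total)
  offset <- stats::rnorm(n_ch, sd = plant$baseline_offset_sd)
  x <- x + offset  # recycled down columns: one offset per channel

  amp_a <- plant$effect_size * plant$noise_sd * if (high_a) 1.5 else 0.5
  amp_v <- plant$effect_size * plant$noise_sd * if (high_v) 1.5 else 0.5
  t_stim <- (n_base:(n_total - 1L)) / fs
  for (ch in plant$planted_channels) {
    if (plant$effect_kind == "oscillation-power") {
      ph <- stats::runif(2, 0, 2 * pi)
      eff <- amp_a * sin(2 * pi * 10 * t_stim + ph[1]) +
             amp_v * sin(2 * pi * 20 * t_stim + ph[2])
    } else {
      eff <- rep(amp_a - amp_v, length(t_stim))
    }
    x[ch, (n_base + 1L):n_total] <- x[ch, (n_base + 1L):n_total] + eff
  }
  if (is.null(trial_id)) trial_id <- sprintf("trial%04d", stream)
  eeg_trial(x, n_baseline = n_base, arousal = arousal, valence = valence,
            subject_id = subject_id, trial_id = trial_id)
}

#' Generate a balanced synthetic dataset in the DEAP layout
#'
#' Generates `4 * n_per_class` trials, exactly `n_per_class` per quadrant
#' class, each 32 x 8064 with 384 baseline samples. Trials are assigned to
#' fixed substreams so an identical [plant_spec()] yields a bit-identical
#' dataset.
#'
#' @param plant a [plant_spec()].
#' @param n_per_class trials per quadrant class (>= 1).
#' @return An object of class `eeg_dataset`: a list with `trials` (list of
#'   [eeg_trial()]), `plant`, and `class_balance` (named count per quadrant).
#' @export
generate_dataset <- function(plant, n_per_class) {
  stopifnot(inherits(plant, "plant_spec"))
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  classes <- rep(QUADRANTS, each = n_per_class)
  trials <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    trials[[i]] <- generate_trial(plant, classes[i], stream = i)
  }
  balance <- vapply(QUADRANTS, function(q) sum(classes == q), integer(1))
  structure(list(trials = trials, plant = plant, class_balance = balance),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat("Synthetic EEG dataset:", length(x$trials), "trials (32 x 8064 @128 Hz)\n")
  cat("  class balance:",
      paste(names(x$class_balance), x$class_balance, sep = "=", collapse = ", "), "\n")
  cat("  planted channels:", paste(x$plant$planted_channels, collapse = ", "),
      " effect_size:", x$plant$effect_size, "\n")
  invisible(x)
}

#' Band-power features of a trial segment
#'
#' Quadrature (sine/cosine projection) power estimate at given frequencies,
#' per channel, over a sample range. Used as the independent feature route
#' when validating the planted oscillatory effect with a linear classifier.
#'
#' @param trial an [eeg_trial()].
#' @param freqs frequencies in Hz.
#' @param channels channel indices (default all).
#' @param segment `"stimulus"` or `"baseline"`.
#' @param fs sampling rate in Hz.
#' @return matrix `length(channels) x length(freqs)` of power estimates.
#' @export
band_power <- function(trial, freqs = c(10, 20), channels = seq_len(nrow(trial$data)),
                       segment = c("stimulus", "baseline"), fs = 128) {
  segment <- match.arg(segment)
  idx <- if (segment == "stimulus")
    (trial$n_baseline + 1L):ncol(trial$data) else seq_len(trial$n_baseline)
  tt <- (idx - 1L) / fs
  out <- matrix(0, length(channels), length(freqs))
  for (j in seq_along(freqs)) {
    s <- sin(2 * pi * freqs[j] * tt); c_ <- cos(2 * pi * freqs[j] * tt)
    xs <- trial$data[channels, idx, drop = FALSE] %*% s
    xc <- trial$data[channels, idx, drop = FALSE] %*% c_
    out[, j] <- (xs^2 + xc^2) * 2 / length(idx)^2
  }
  out
}
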