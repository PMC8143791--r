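# ---- EEG preprocessing: filtering, normalization, windowing ---------------

#' Filter a trial, compensate group delay, and resample
#'
#' Each EEG channel is convolved with the (linear-phase) filter coefficients,
#' advanced by the filter's group delay (edges zero-padded) so the output is
#' time-aligned with the input, then resampled to `fs_target` by Fourier
#' resampling.  The bandpass itself provides the anti-alias protection: its
#' upper stopband lies at or below the target Nyquist rate.
#'
#' @param trial an `aad_trial` (see [generate_trial()]).
#' @param filt an `fir_filter` from [design_bandpass()], designed at the
#'   trial's sampling rate.
#' @param fs_target output sampling rate in Hz (128 for the CNN pathway,
#'   20 for the linear pathway).
#' @param stimuli if `TRUE`, the stimulus envelopes stored in the trial are
#'   filtered and resampled the same way as the EEG.
#' @return the trial with filtered, resampled `eeg` (and stimuli) and
#'   updated `fs`.
#' @export
filter_compensate_resample <- function(trial, filt, fs_target,
                                       stimuli = FALSE) {
  stopifnot(inherits(trial, "aad_trial"), inherits(filt, "fir_filter"))
  if (!isTRUE(all.equal(trial$fs, filt$fs))) {
    stop("filter was designed at ", filt$fs, " Hz but trial is sampled at ",
         trial$fs, " Hz")
  }
  h <- filt$coefficients
  y <- .fft_filter_rows(trial$eeg, h, filt$group_delay)
  trial$eeg <- fft_resample(y, trial$fs, fs_target)
  if (stimuli && !is.null(trial$stimulus_left)) {
    st <- rbind(trial$stimulus_left, trial$stimulus_right)
    st <- .fft_filter_rows(st, h, filt$group_delay)
    st <- fft_resample(st, trial$fs, fs_target)
    trial$stimulus_left <- st[1, ]
    trial$stimulus_right <- st[2, ]
  }
  trial$fs <- fs_target
  trial
}

#' Robust channel power: trimmed mean of squared samples
#'
#' Squares the samples, discards the lowest and highest 5% (floor of
#' `0.05 * n` per tail; a 10% total trim), and returns the mean of the rest.
#'
#' @param x numeric vector of at least 20 samples (so at least one sample is
#'   trimmed per tail).
#' @return scalar power estimate.
#' @examples
#' trimmed_power(rep(2, 100))  # 4
#' @export
trimmed_power <- function(x) {
  n <- length(x)
  if (n < 20) stop("trimmed_power() needs at least 20 samples")
  sq <- sort(x^2)
  k <- floor(0.05 * n)
  mean(sq[(k + 1):(n - k)])
}

#' Subject-wise normalization from training-set statistics
#'
#' Computes the per-channel power (trimmed mean of squared samples) over the
#' concatenated training trials, takes the square root of the median of the
#' 64 channel powers as a single subject-specific scale, and divides every
#' supplied trial by that scale.  Channel proportions are therefore
#' preserved.  Test trials must never contribute to the statistics: the
#' training subset is identified by index and checked.
#'
#' @param trials list of `aad_trial` objects from one subject.
#' @param training_idx integer indices into `trials` marking the training
#'   trials (statistics are computed from these only).
#' @param training_fraction optional fraction (0, 1] of each training trial's
#'   leading samples to use for the statistics, for splits where only the
#'   leading portion of a trial is training data.
#' @return list with `trials` (all trials, scaled) and `scale` (the scalar
#'   divisor) and `channel_power` (the 64 training powers before scaling).
#' @export
normalize_subject <- function(trials, training_idx,
                              training_fraction = 1) {
  stopifnot(length(trials) > 0, length(training_idx) > 0,
            all(training_idx >= 1), all(training_idx <= length(trials)),
            training_fraction > 0, training_fraction <= 1)
  subj <- unique(vapply(trials, function(t) t$subject_id, numeric(1)))
  if (length(subj) != 1) {
    stop("normalize_subject() expects trials from a single subject")
  }
  train_mats <- lapply(trials[training_idx], function(t) {
    n_use <- max(20L, floor(ncol(t$eeg) * training_fraction))
    t$eeg[, seq_len(min(n_use, ncol(t$eeg))), drop = FALSE]
  })
  eeg <- do.call(cbind, train_mats)
  powers <- apply(eeg, 1, trimmed_power)
  scale <- sqrt(stats::median(powers))
  if (!is.finite(scale) || scale == 0) {
    stop("degenerate input: training channel powers have zero median")
  }
  trials <- lapply(trials, function(t) {
    t$eeg <- t$eeg / scale
    t
  })
  list(trials = trials, scale = scale, channel_power = powers)
}

#' Segment a trial into 50%-overlapping decision windows
#'
#' Slides a window of `round(window_seconds * fs)` samples over the trial
#' with a hop of half the window (floor), producing
#' `floor((N - T) / hop) + 1` windows that all inherit the trial's
#' attended-ear label.
#'
#' @param trial an `aad_trial` (at the model sampling rate).
#' @param window_seconds decision window length in seconds.
#' @param overlap fixed at 0.5.
#' @param range optional `c(first, last)` sample range (1-based, inclusive)
#'   to segment instead of the whole trial, used by the split schemes so that
#'   windows never straddle train/validation/test boundaries.
#' @return a `decision_windows` object: list with `x` (array
#'   channels x T x n), `label` (factor left/right), `subject_id`,
#'   `trial_id`, `start_sample`, `fs`, `T`.
#' @export
segment_windows <- function(trial, window_seconds, overlap = 0.5,
                            range = NULL) {
  stopifnot(inherits(trial, "aad_trial"))
  if (!isTRUE(all.equal(overlap, 0.5))) {
    stop("only 50% overlap is supported")
  }
  x <- trial$eeg
  if (!is.null(range)) {
    stopifnot(length(range) == 2, range[1] >= 1, range[2] <= ncol(x),
              range[1] < range[2])
    x <- x[, range[1]:range[2], drop = FALSE]
    offset <- range[1] - 1L
  } else {
    offset <- 0L
  }
  N <- ncol(x)
  T_len <- as.integer(round(window_seconds * trial$fs))
  if (T_len < 1) stop("window too short for sampling rate")
  if (T_len > N) stop("window (", T_len, " samples) longer than segment (",
                      N, " samples)")
  hop <- T_len %/% 2L
  n_win <- (N - T_len) %/% hop + 1L
  arr <- array(0, dim = c(nrow(x), T_len, n_win))
  starts <- integer(n_win)
  for (i in seq_len(n_win)) {
    s <- (i - 1L) * hop + 1L
    starts[i] <- s + offset
    arr[, , i] <- x[, s:(s + T_len - 1L)]
  }
  structure(list(
    x = arr,
    label = factor(rep(trial$attended_ear, n_win),
                   levels = c("left", "right")),
    subject_id = rep(trial$subject_id, n_win),
    trial_id = rep(trial$trial_id, n_win),
    start_sample = starts,
    fs = trial$fs, T = T_len
  ), class = "decision_windows")
}

#' Concatenate decision-window sets
#'
#' @param ... `decision_windows` objects (or a single list of them) with
#'   identical channel counts, window lengths and sampling rates.
#' @return a single `decision_windows` object.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "decision_windows")) {
    parts <- parts[[1]]
  }
  parts <- Filter(function(p) !is.null(p) && length(p$label) > 0, parts)
  stopifnot(length(parts) > 0)
  T_len <- unique(vapply(parts, function(p) p$T, integer(1)))
  fs <- unique(vapply(parts, function(p) p$fs, numeric(1)))
  stopifnot(length(T_len) == 1, length(fs) == 1)
  n <- sum(vapply(parts, function(p) length(p$label), integer(1)))
  nch <- dim(parts[[1]]$x)[1]
  arr <- array(0, dim = c(nch, T_len, n))
  at <- 0L
  for (p in parts) {
    k <- length(p$label)
    arr[, , at + seq_len(k)] <- p$x
    at <- at + k
  }
  structure(list(
    x = arr,
    label = factor(unlist(lapply(parts, function(p) as.character(p$label))),
                   levels = c("left", "right")),
    subject_id = unlist(lapply(parts, function(p) p$subject_id)),
    trial_id = unlist(lapply(parts, function(p) p$trial_id)),
    start_sample = unlist(lapply(parts, function(p) p$start_sample)),
    fs = fs, T = T_len
  ), class = "decision_windows")
}

#' @export
print.decision_windows <- function(x, ...) {
  cat(sprintf("%d decision windows of %d samples (%.3g s at %g Hz)\n",
              length(x$label), x$T, x$T / x$fs, x$fs))
  print(table(x$label))
  invisible(x)
}

#' Artifact-removal hook
#'
#' Marks the stage where a multi-channel Wiener-filter (MWF) based artifact
#' suppression would run on real recordings.  The method itself is external
#' to this package: `"none"` is the identity, and `"external"` applies a
#' user-supplied function `trial -> trial`.
#'
#' @param trial an `aad_trial`.
#' @param method `"none"` or `"external"`.
#' @param fn function applied when `method = "external"`.
#' @export
remove_artifacts <- function(trial, method = c("none", "external"),
                             fn = NULL) {
  method <- match.arg(method)
  if (method == "none") return(trial)
  if (!is.function(fn)) stop("method = 'external' needs a function `fn`")
  out <- fn(trial)
  stopifnot(inherits(out, "aad_trial"))
  out
}
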