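# ---- Linear stimulus-reconstruction baseline ------------------------------
#
# Backward (decoding) model: a spatio-temporal filter over the EEG and its
# time-shifted versions up to 250 ms (6 lags at 20 Hz), least-squares fitted
# to reconstruct the attended speech envelope.  Per-window classification
# correlates the reconstruction with both speaker envelopes (Pearson) and
# picks the larger.  Envelopes of real audio are computed as power-law
# (exponent 0.6) compressed gammatone subband envelopes, summed with unit
# coefficients.

#' Gammatone filterbank kernels
#'
#' Fourth-order gammatone impulse responses with center frequencies equally
#' spaced on the ERB-rate scale (Glasberg & Moore) between `f_lo` and
#' `f_hi`, each normalized to unit gain at its center frequency.
#'
#' @param fs_audio audio sampling rate in Hz (>= 8 kHz).
#' @param n_bands number of subbands.
#' @param f_lo,f_hi center-frequency range in Hz.
#' @return list with `kernels` (list of numeric vectors), `cf` (center
#'   frequencies).
#' @export
gammatone_filterbank <- function(fs_audio, n_bands = 15, f_lo = 150,
                                 f_hi = 4000) {
  stopifnot(fs_audio >= 8000, n_bands >= 1, f_lo > 0, f_hi > f_lo,
            f_hi <= fs_audio / 2)
  erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)
  erb_rate_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437
  cf <- erb_rate_inv(seq(erb_rate(f_lo), erb_rate(f_hi),
                         length.out = n_bands))
  kernels <- lapply(cf, function(f) {
    b <- 1.019 * 24.7 * (1 + 4.37 * f / 1000)   # ERB bandwidth
    dur <- min(0.05, 12 / (2 * pi * b))          # envelope decayed to ~e^-12
    t <- seq(0, dur, by = 1 / fs_audio)[-1]
    g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * f * t)
    # unit gain at the center frequency
    H <- sum(g * exp(-2i * pi * f * t))
    g / Mod(H)
  })
  list(kernels = kernels, cf = cf)
}

#' Power-law subband envelope of a speech waveform
#'
#' Splits the audio with a gammatone filterbank, compresses each subband
#' magnitude envelope with exponent 0.6, sums the subbands with unit
#' coefficients, then filters and downsamples the result in the same vein
#' as the EEG of the linear pathway (1-9 Hz bandpass, 20 Hz).  Because the
#' summed envelope is already far smoother than the audio, the bandpass is
#' applied at an intermediate envelope rate (128 Hz by default), which is
#' equivalent for the band of interest and much cheaper than designing the
#' 1-9 Hz filter at the audio rate.
#'
#' @param audio numeric waveform.
#' @param fs_audio audio sampling rate in Hz (>= 8 kHz).
#' @param fs_out output envelope rate (20 Hz for the linear decoder).
#' @param fs_envelope intermediate rate at which the 1-9 Hz bandpass is
#'   applied.
#' @param compress power-law exponent.
#' @param filterbank optionally a precomputed [gammatone_filterbank()].
#' @param bandpass `TRUE` to apply the 1-9 Hz stage, `FALSE` to return the
#'   raw compressed-sum envelope at `fs_out` (used by unit tests of the
#'   subband stage).
#' @return numeric envelope at `fs_out`.
#' @export
powerlaw_envelope <- function(audio, fs_audio, fs_out = 20,
                              fs_envelope = 128, compress = 0.6,
                              filterbank = NULL, bandpass = TRUE) {
  if (length(audio) == 0) stop("empty audio")
  stopifnot(fs_audio >= 8000)
  if (is.null(filterbank)) filterbank <- gammatone_filterbank(fs_audio)
  env <- numeric(length(audio))
  for (g in filterbank$kernels) {
    sub <- .fft_filter_rows(matrix(audio, 1), g, 0L)[1, ]
    env <- env + abs(sub)^compress
  }
  env_lo <- fft_resample(env, fs_audio, fs_envelope)
  if (bandpass) {
    filt <- .envelope_bandpass(fs_envelope)
    env_lo <- .fft_filter_rows(matrix(env_lo, 1), filt$coefficients,
                               filt$group_delay)[1, ]
  }
  fft_resample(env_lo, fs_envelope, fs_out)
}

# cached 1-9 Hz envelope filter designs, keyed by sampling rate
.envelope_filter_cache <- new.env(parent = emptyenv())
.envelope_bandpass <- function(fs) {
  key <- as.character(fs)
  if (is.null(.envelope_filter_cache[[key]])) {
    .envelope_filter_cache[[key]] <- design_bandpass(linear_bandpass_spec(fs))
  }
  .envelope_filter_cache[[key]]
}

# stack EEG lags: rows are (lag block l = 0..L-1) x channels, columns are
# the valid time points 1..(N-L+1); reconstruction at time t uses
# eeg[, t + l] (post-stimulus EEG trails the attended envelope)
.lag_matrix <- function(eeg, n_lags) {
  nch <- nrow(eeg); N <- ncol(eeg)
  if (N < n_lags) stop("window shorter than the decoder kernel (", n_lags,
                       " samples)")
  n_valid <- N - n_lags + 1L
  X <- matrix(0, nch * n_lags, n_valid)
  for (l in seq_len(n_lags)) {
    X[(l - 1L) * nch + seq_len(nch), ] <-
      eeg[, (l - 1L) + seq_len(n_valid), drop = FALSE]
  }
  X
}

#' Fit the backward linear decoder by least squares
#'
#' Solves the normal equations `R w = r` where `R` is the autocorrelation
#' matrix of the lagged EEG (lags 0-250 ms, i.e. 6 samples at 20 Hz) and
#' `r` its cross-correlation with the attended envelope, accumulated over
#' the supplied training pairs.  Per the evaluation protocol the decoder is
#' subject-specific: pass only one subject's training data.
#'
#' @param eeg_list list of EEG matrices (channels x samples) at the decoder
#'   rate (20 Hz).
#' @param envelope_list list of attended envelopes aligned with each EEG
#'   matrix.
#' @param n_lags number of lags (6 = floor(0.25 s * 20 Hz) + 1).
#' @param ridge optional ridge penalty added to the diagonal (default 0:
#'   plain least squares).
#' @return a `linear_decoder`: list with `weights` (channels x lags matrix),
#'   `n_lags`, `fs`.
#' @export
fit_linear_decoder <- function(eeg_list, envelope_list, n_lags = 6L,
                               ridge = 0, fs = 20) {
  stopifnot(length(eeg_list) == length(envelope_list),
            length(eeg_list) >= 1)
  nch <- nrow(eeg_list[[1]])
  p <- nch * n_lags
  R <- matrix(0, p, p)
  r <- numeric(p)
  for (i in seq_along(eeg_list)) {
    X <- .lag_matrix(eeg_list[[i]], n_lags)
    d <- envelope_list[[i]][seq_len(ncol(X))]
    R <- R + X %*% t(X)
    r <- r + X %*% d
  }
  if (ridge > 0) R <- R + diag(ridge, p)
  w <- tryCatch(solve(R, r), error = function(e) {
    warning("rank-deficient normal equations; using pseudo-inverse")
    sv <- svd(R)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% r) / sv$d[pos])
  })
  structure(list(weights = matrix(w, nch, n_lags), n_lags = as.integer(n_lags),
                 fs = fs),
            class = "linear_decoder")
}

#' Reconstruct the attended envelope from an EEG window
#'
#' @param decoder a `linear_decoder`.
#' @param eeg EEG matrix (channels x samples) at the decoder rate.
#' @return reconstructed envelope (length `ncol(eeg) - n_lags + 1`; the lag
#'   overhang is truncated, not padded).
#' @export
reconstruct_envelope <- function(decoder, eeg) {
  X <- .lag_matrix(eeg, decoder$n_lags)
  as.vector(t(as.vector(decoder$weights)) %*% X)
}

#' Classify one decision window by envelope correlation
#'
#' Correlates the reconstruction (Pearson) with both speaker envelopes and
#' returns the side with the higher correlation; exact ties, or degenerate
#' zero-variance inputs, resolve to `"left"` and are flagged.
#'
#' @param decoder a `linear_decoder`.
#' @param eeg EEG window (channels x samples, >= `n_lags` samples).
#' @param env_left,env_right candidate envelopes over the same window.
#' @return list with `label`, `cor_left`, `cor_right`, `degenerate`.
#' @export
classify_window_linear <- function(decoder, eeg, env_left, env_right) {
  rec <- reconstruct_envelope(decoder, eeg)
  nv <- length(rec)
  el <- env_left[seq_len(nv)]
  er <- env_right[seq_len(nv)]
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  cl <- safe_cor(rec, el)
  cr <- safe_cor(rec, er)
  degenerate <- is.na(cl) || is.na(cr)
  label <- if (degenerate) "left" else if (cr > cl) "right" else "left"
  list(label = label, cor_left = cl, cor_right = cr, degenerate = degenerate)
}

#' Evaluate the linear decoder over segmented decision windows
#'
#' The decoder is applied to each whole test trial once (so the 250 ms
#' kernel only truncates the trial tail, not every window), then
#' 50%-overlapping decision windows of the reconstruction are correlated
#' with both speaker envelopes.  The kernel width places the lower bound on
#' usable window lengths: windows must span at least 250 ms (5 samples at
#' 20 Hz).
#'
#' @param decoder a `linear_decoder`.
#' @param trials list of `aad_trial` objects at the decoder rate, with
#'   `stimulus_left`/`stimulus_right` holding the envelopes at the same
#'   rate.
#' @param window_seconds decision window length (>= 0.25 s).
#' @param range_fraction optional `c(lo, hi)` fraction of each trial to use
#'   (e.g. the test segment of an every-trial split).
#' @return list with `accuracy` (percent), `n_windows`, `decisions`
#'   (data frame).
#' @export
evaluate_linear <- function(decoder, trials, window_seconds,
                            range_fraction = NULL) {
  T_len <- as.integer(round(window_seconds * decoder$fs))
  if (T_len < decoder$n_lags - 1L) {
    stop("decision window shorter than the 250 ms decoder kernel")
  }
  rows <- list()
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  for (tr in trials) {
    N <- ncol(tr$eeg)
    rec <- reconstruct_envelope(decoder, tr$eeg)   # length N - n_lags + 1
    n_rec <- length(rec)
    rng <- if (is.null(range_fraction)) c(1L, N) else
      c(max(1L, floor(range_fraction[1] * N) + 1L),
        floor(range_fraction[2] * N))
    hop <- max(1L, T_len %/% 2L)
    n_win <- (rng[2] - rng[1] + 1L - T_len) %/% hop + 1L
    if (n_win < 1) next
    for (i in seq_len(n_win)) {
      s <- rng[1] + (i - 1L) * hop
      idx <- s:min(s + T_len - 1L, n_rec)
      if (length(idx) < max(3L, T_len %/% 2L)) next
      cl <- safe_cor(rec[idx], tr$stimulus_left[idx])
      cr <- safe_cor(rec[idx], tr$stimulus_right[idx])
      degenerate <- is.na(cl) || is.na(cr)
      label <- if (degenerate) "left" else if (cr > cl) "right" else "left"
      rows[[length(rows) + 1L]] <- data.frame(
        subject = tr$subject_id, trial = tr$trial_id, start = s,
        label = label, truth = tr$attended_ear,
        cor_left = cl, cor_right = cr, degenerate = degenerate)
    }
  }
  dec <- do.call(rbind, rows)
  if (is.null(dec)) stop("no decision windows produced")
  list(accuracy = 100 * mean(dec$label == dec$truth),
       n_windows = nrow(dec), decisions = dec)
}
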