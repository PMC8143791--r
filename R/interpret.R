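# ---- Interpretation analyses: band ablation and filter topography ---------

#' Canonical EEG frequency bands within the 1-32 Hz decoding range
#'
#' @return data frame with `name` (delta, theta, alpha, beta) and `f1`,
#'   `f2` in Hz (1-4, 4-8, 8-14, 14-32).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             f1 = c(1, 4, 8, 14),
             f2 = c(4, 8, 14, 32),
             stringsAsFactors = FALSE)
}

# zero-phase band-stop / band-pass filter for ablation at the model rate;
# linear-phase FIR applied with group-delay compensation (hence zero phase),
# 20 dB stopbands, 0.5 dB passband ripple, 0.5 Hz transitions
.ablation_filter_cache <- new.env(parent = emptyenv())
.ablation_filter <- function(band, mode, fs) {
  key <- paste(band[1], band[2], mode, fs, sep = "_")
  if (!is.null(.ablation_filter_cache[[key]])) {
    return(.ablation_filter_cache[[key]])
  }
  tw <- 0.5
  dp <- 1 - 10^(-0.5 / 20)
  ds <- 10^(-20 / 20)
  nyq <- fs / 2
  if (mode == "remove") {
    bands <- data.frame(f1 = numeric(0), f2 = numeric(0), gain = numeric(0),
                        ripple = numeric(0))
    if (band[1] - tw > 0.25) {
      bands <- rbind(bands, data.frame(f1 = 0, f2 = band[1] - tw, gain = 1,
                                       ripple = dp))
    }
    bands <- rbind(bands, data.frame(f1 = band[1], f2 = band[2], gain = 0,
                                     ripple = ds))
    if (band[2] + tw < nyq) {
      bands <- rbind(bands, data.frame(f1 = band[2] + tw, f2 = nyq,
                                       gain = 1, ripple = dp))
    }
  } else {
    bands <- data.frame(f1 = band[1], f2 = band[2], gain = 1, ripple = dp)
    if (band[1] - tw > 0.25) {
      bands <- rbind(data.frame(f1 = 0, f2 = band[1] - tw, gain = 0,
                                ripple = ds), bands)
    }
    if (band[2] + tw < nyq) {
      bands <- rbind(bands, data.frame(f1 = band[2] + tw, f2 = nyq,
                                       gain = 0, ripple = ds))
    }
  }
  n <- 15L
  repeat {
    d <- fir_design_minimax(n, fs, bands)
    if (d$converged) break
    n <- as.integer(n * 1.4)
    if (n %% 2 == 0) n <- n + 1L
    if (n > 20001) stop("ablation filter design failed")
  }
  filt <- list(h = d$h, delay = (length(d$h) - 1L) %/% 2L)
  .ablation_filter_cache[[key]] <- filt
  filt
}

#' Retest frozen models on band-filtered EEG
#'
#' Re-filters the continuous test trials (band-stop for `mode = "remove"`,
#' band-pass for `mode = "keep"`; zero-phase), re-segments them exactly as
#' before, and evaluates the already-trained models without retraining.
#'
#' @param models list of `trained_cnn` / `cnn_model` objects trained on the
#'   wide-band (1-32 Hz) data.
#' @param test_trials list of continuous, preprocessed and normalized
#'   `aad_trial` objects at the model rate (filtering precedes windowing).
#' @param band numeric `c(f1, f2)` within 1-32 Hz, or a band name from
#'   [eeg_bands()].
#' @param mode `"remove"` (filter the band out) or `"keep"` (filter
#'   everything else out).
#' @param window_seconds decision window length used for segmentation.
#' @return list with `accuracy` (percent, mean over models) and
#'   `per_model`.
#' @export
band_ablation_retest <- function(models, test_trials, band,
                                 mode = c("remove", "keep"),
                                 window_seconds = 1) {
  mode <- match.arg(mode)
  if (is.character(band)) {
    bd <- eeg_bands()
    row <- bd[bd$name == band, ]
    if (nrow(row) != 1) stop("unknown band name: ", band)
    band <- c(row$f1, row$f2)
  }
  if (band[1] < 1 || band[2] > 32 || band[1] >= band[2]) {
    stop("band must lie within 1-32 Hz")
  }
  fs <- test_trials[[1]]$fs
  filt <- .ablation_filter(band, mode, fs)
  filtered <- lapply(test_trials, function(tr) {
    tr$eeg <- .fft_filter_rows(tr$eeg, filt$h, filt$delay)
    tr
  })
  wins <- bind_windows(lapply(filtered, segment_windows,
                              window_seconds = window_seconds))
  ev <- evaluate_cnn(models, wins)
  list(accuracy = ev$accuracy, per_model = ev$per_model)
}

#' Grand-average convolutional filter topography
#'
#' Per model, the power of the convolutional filter weights is averaged per
#' channel (over the 5 filters and 17 taps); the per-channel powers are
#' grand-averaged over models and then normalized with the per-channel
#' power of the EEG in the training set.  The default combination
#' multiplies by the training channel power (the convolution output power
#' reflects both the weights and the input magnitude); division is exposed
#' as an alternative reading.
#'
#' @param models list of `trained_cnn` / `cnn_model` objects.
#' @param training_channel_powers numeric vector (one power per channel,
#'   all > 0), e.g. `channel_power` from [normalize_subject()].
#' @param combine `"multiply"` or `"divide"`.
#' @param labels channel labels for the map.
#' @return a `topo_map`: list with `values` (nonnegative, one per channel)
#'   and `labels`.
#' @export
filter_topography <- function(models, training_channel_powers,
                              combine = c("multiply", "divide"),
                              labels = NULL) {
  combine <- match.arg(combine)
  if (inherits(models, "trained_cnn") || inherits(models, "cnn_model")) {
    models <- list(models)
  }
  stopifnot(length(models) >= 1)
  if (any(!is.finite(training_channel_powers)) ||
      any(training_channel_powers <= 0)) {
    stop("degenerate input: training channel powers must be positive")
  }
  per_model <- vapply(models, function(m) {
    if (inherits(m, "trained_cnn")) m <- m$model
    apply(m$conv_w^2, 2, mean)  # mean over filters and taps, per channel
  }, numeric(length(training_channel_powers)))
  grand <- rowMeans(per_model)
  values <- if (combine == "multiply") grand * training_channel_powers else
    grand / training_channel_powers
  if (is.null(labels)) {
    labels <- if (length(values) == 64) biosemi64_labels() else
      paste0("ch", seq_along(values))
  }
  structure(list(values = values, labels = labels), class = "topo_map")
}

#' @export
print.topo_map <- function(x, ...) {
  ord <- order(x$values, decreasing = TRUE)
  cat("topographic map; strongest channels:",
      paste(x$labels[ord[1:min(8, length(ord))]], collapse = ", "), "\n")
  invisible(x)
}
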