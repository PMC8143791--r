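# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  Keeps every stochastic operation in the
# package reproducible from explicit seeds without clobbering user RNG.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministically derive a child seed in [1, 2^31 - 2] from a parent seed
# and a stream of integer tags (subject, trial, run, ...).
.derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + (as.numeric(t) %% 2147483647)) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# FFT-based convolution of each matrix row with kernel h, "full" length,
# returning the segment aligned with the input after removing `delay`
# leading samples (group-delay compensation; edges are zero-padded).
.fft_filter_rows <- function(x, h, delay) {
  n <- ncol(x)
  L <- length(h)
  nfft <- stats::nextn(n + L - 1L, 2)
  H <- stats::fft(c(h, numeric(nfft - L)))
  X <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), nfft - n))))
  Y <- X * H
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
  t(y)[, (delay + 1L):(delay + n), drop = FALSE]
}

#' Fourier resampling of band-limited signals
#'
#' Resamples each row of `x` from `fs_in` to `fs_out` by spectral truncation
#' (or zero-padding), exact for signals band-limited below the lower of the
#' two Nyquist rates.  Used after bandpass filtering, where the passband
#' guarantees band-limitation, so no separate anti-alias stage is needed.
#'
#' @param x numeric matrix (channels x samples) or vector.
#' @param fs_in,fs_out sampling rates in Hz.
#' @return resampled matrix (or vector) with `round(n * fs_out / fs_in)`
#'   samples.
#' @export
fft_resample <- function(x, fs_in, fs_out) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n_in <- ncol(x)
  n_out <- as.integer(round(n_in * fs_out / fs_in))
  if (n_out == n_in && fs_in == fs_out) {
    return(if (vec) drop(x) else x)
  }
  X <- stats::mvfft(t(x))
  Y <- matrix(0 + 0i, n_out, nrow(x))
  keep <- min(n_in, n_out)
  h1 <- ceiling((keep - 1) / 2)    # positive-frequency bins kept
  h2 <- floor((keep - 1) / 2)      # negative-frequency bins kept
  Y[1:(h1 + 1), ] <- X[1:(h1 + 1), , drop = FALSE]
  if (h2 > 0) {
    Y[(n_out - h2 + 1):n_out, ] <- X[(n_in - h2 + 1):n_in, , drop = FALSE]
  }
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / n_in
  out <- t(y)
  if (vec) drop(out) else out
}
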