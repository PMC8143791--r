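test_that("power-law subband envelope follows amplitude modulation", {
  fs <- 8000
  t <- seq_len(fs * 4) / fs
  fb <- gammatone_filterbank(fs)
  expect_length(fb$kernels, 15)
  expect_equal(range(fb$cf), c(150, 4000), tolerance = 1e-6)
  # 4 Hz AM tone: envelope's dominant modulation frequency is 4 Hz
  x <- (1 + 0.9 * sin(2 * pi * 4 * t)) * sin(2 * pi * 1000 * t)
  env <- powerlaw_envelope(x, fs, fs_out = 20, filterbank = fb)
  sp <- Mod(stats::fft(env - mean(env)))[2:floor(length(env) / 2)]
  f_axis <- (2:floor(length(env) / 2) - 1) * 20 / length(env)
  expect_equal(f_axis[which.max(sp)], 4, tolerance = 0.3)
  # zero waveform -> zero envelope
  expect_true(all(powerlaw_envelope(numeric(1000) + 0, fs,
                                    filterbank = fb) == 0))
  expect_error(powerlaw_envelope(numeric(0), fs), "empty")
})

test_that("subband compression is power-law homogeneous before filtering", {
  fs <- 8000
  set.seed(2)
  x <- rnorm(fs)
  fb <- gammatone_filterbank(fs, n_bands = 4)
  e1 <- powerlaw_envelope(x, fs, filterbank = fb, bandpass = FALSE)
  e2 <- powerlaw_envelope(2 * x, fs, filterbank = fb, bandpass = FALSE)
  expect_equal(e2, 2^0.6 * e1, tolerance = 1e-8)
})

test_that("least-squares decoder equals the pseudo-inverse oracle and has shape 64 x 6", {
  set.seed(4)
  eeg <- matrix(rnorm(5 * 200), 5)
  env <- rnorm(195)
  dec <- fit_linear_decoder(list(eeg), list(env), n_lags = 6)
  X <- aadecode:::.lag_matrix(eeg, 6)
  w_oracle <- MASS_ginv_free <- qr.solve(t(X), env)   # lstsq via QR
  expect_equal(as.vector(dec$weights), as.vector(w_oracle),
               tolerance = 1e-8)
  dec64 <- fit_linear_decoder(list(matrix(rnorm(64 * 400), 64)),
                              list(rnorm(395)))
  expect_equal(dim(dec64$weights), c(64L, 6L))
})

test_that("a noiseless forward model is inverted almost perfectly", {
  set.seed(9)
  env <- as.vector(stats::filter(rnorm(2000), rep(1, 10),
                                 method = "convolution", sides = 1))
  env[is.na(env)] <- 0
  topo <- seq(0.5, 2, length.out = 8)
  eeg <- outer(topo, env)                 # channels follow the envelope
  # a rank-1 forward model makes the normal equations singular: the
  # pseudo-inverse fallback must engage (with its warning) and still invert
  expect_warning(
    dec <- fit_linear_decoder(list(eeg), list(env), n_lags = 6),
    "pseudo-inverse")
  rec <- reconstruct_envelope(dec, eeg)
  expect_gte(stats::cor(rec, env[seq_along(rec)]), 0.99)
})

test_that("window classification follows the larger Pearson correlation", {
  set.seed(12)
  env <- rnorm(100)
  eeg <- rbind(env + rnorm(100, sd = 1e-3), rnorm(100))
  dec <- fit_linear_decoder(list(eeg), list(env), n_lags = 2)
  noise <- rnorm(100)
  res <- classify_window_linear(dec, eeg, env, noise)
  expect_equal(res$label, "left")
  expect_false(res$degenerate)
  res2 <- classify_window_linear(dec, eeg, noise, env)
  expect_equal(res2$label, "right")
  # correlations match the covariance-formula oracle
  rec <- reconstruct_envelope(dec, eeg)
  nv <- length(rec)
  oracle_cor <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  }
  expect_equal(res$cor_left, oracle_cor(rec, env[1:nv]), tolerance = 1e-12)
  expect_equal(res$cor_right, oracle_cor(rec, noise[1:nv]),
               tolerance = 1e-12)
  expect_equal(stats::cor(c(1, 2, 3), c(1, 2, 3)), 1)
  # zero-variance envelope: flagged degenerate, tie-break to left
  res3 <- classify_window_linear(dec, eeg, rep(1, 100), noise)
  expect_true(res3$degenerate)
  expect_equal(res3$label, "left")
})

test_that("reconstruction is linear and correlations scale-invariant", {
  set.seed(13)
  eeg <- matrix(rnorm(4 * 120), 4)
  env <- rnorm(120)
  dec <- fit_linear_decoder(list(eeg), list(env), n_lags = 3)
  r1 <- reconstruct_envelope(dec, eeg)
  r2 <- reconstruct_envelope(dec, 3 * eeg)
  expect_equal(r2, 3 * r1, tolerance = 1e-12)
  a <- classify_window_linear(dec, eeg, env, rev(env))
  b <- classify_window_linear(dec, 5 * eeg, 2 * env, 7 * rev(env))
  expect_equal(a$cor_left, b$cor_left, tolerance = 1e-12)
  expect_equal(a$cor_right, b$cor_right, tolerance = 1e-12)
})

test_that("linear decoding beats chance on synthetic data without any spatial cue", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 8,
                      trial_duration = 60, fs_native = 512,
                      lateralization_gain = 0, envelope_snr = -6,
                      seed = 31)
  ds <- generate_dataset(cfg)
  pre <- preprocess_dataset(ds, "linear")
  res <- run_experiment(pre, model = "linear", scheme = "story_speaker",
                        windows = 10)
  expect_gt(mean(res$accuracy), 65)
  # and the kernel width bounds the usable window lengths
  res13 <- run_experiment(pre, model = "linear", scheme = "story_speaker",
                          windows = c(10, 0.13))
  expect_true(all(res13$window_seconds == 10))
})
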