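make_trial <- function(eeg, fs, ear = "left", subject = 1, trial = 1) {
  structure(list(eeg = eeg, fs = fs, subject_id = subject, trial_id = trial,
                 story_id = 1, speaker_id = 1, attended_ear = ear,
                 presentation = "dichotic"),
            class = "aad_trial")
}

test_that("group-delay compensation re-aligns an impulse with its origin", {
  filt <- test_cnn_filter(512)
  n <- 512 * 8
  x <- matrix(0, 2, n)
  pos <- 2000L
  x[, pos] <- 1
  tr <- filter_compensate_resample(make_trial(x, 512), filt, 512)
  expect_equal(which.max(abs(tr$eeg[1, ])), pos)
  expect_equal(which.max(abs(tr$eeg[2, ])), pos)
})

test_that("a 10 Hz passband tone passes at unity gain; DC is attenuated >= 20 dB", {
  filt <- test_cnn_filter(512)
  fs <- 512
  n <- 20 * fs
  t <- seq_len(n) / fs
  mid <- (5 * fs):(15 * fs)   # central region, away from edge transients
  tone <- matrix(sin(2 * pi * 10 * t), 1)
  out <- filter_compensate_resample(make_trial(tone, fs), filt, fs)$eeg
  gain_db <- 20 * log10(sqrt(mean(out[1, mid]^2)) /
                          sqrt(mean(tone[1, mid]^2)))
  expect_lt(abs(gain_db), 0.5)
  dc <- matrix(1, 1, n)
  out_dc <- filter_compensate_resample(make_trial(dc, fs), filt, fs)$eeg
  atten_db <- -20 * log10(sqrt(mean(out_dc[1, mid]^2)))
  expect_gte(atten_db, 20)
})

test_that("filtering requires a filter designed at the trial rate", {
  filt <- test_cnn_filter(512)
  tr <- make_trial(matrix(rnorm(256 * 4), 4), 256)
  expect_error(filter_compensate_resample(tr, filt, 128), "designed at")
})

test_that("Fourier resampling preserves band-limited content", {
  fs <- 512
  t <- (seq_len(fs * 4) - 1) / fs          # output samples share t = 0 origin
  x <- matrix(sin(2 * pi * 7 * t) + 0.5 * cos(2 * pi * 20 * t), 1)
  y <- fft_resample(x, fs, 128)
  expect_equal(ncol(y), 128 * 4)
  t2 <- (seq_len(128 * 4) - 1) / 128
  ref <- sin(2 * pi * 7 * t2) + 0.5 * cos(2 * pi * 20 * t2)
  expect_lt(max(abs(y[1, ] - ref)), 1e-6)
})

test_that("trimmed power matches a brute-force sort-and-average oracle", {
  expect_equal(trimmed_power(rep(2, 100)), 4)
  x <- c(1:10, 1000, 1:9)            # n = 20, one sample trimmed per tail
  oracle <- function(v) {
    sq <- sort(v^2)
    k <- floor(0.05 * length(v))
    mean(sq[(k + 1):(length(v) - k)])
  }
  expect_equal(trimmed_power(x), oracle(x))
  set.seed(42)
  y <- rnorm(1000)
  y_out <- c(y[-1], 1e6)             # one extreme outlier
  expect_lt(abs(trimmed_power(y_out) - trimmed_power(y)) /
              trimmed_power(y), 0.01)
  expect_error(trimmed_power(rnorm(10)), "at least 20")
})

test_that("subject normalization divides by sqrt(median channel power)", {
  # 2-channel toy with constant channels 1 and 2: powers {1, 4}, median 2.5
  eeg <- rbind(rep(1, 100), rep(2, 100))
  tr <- make_trial(eeg, 100)
  out <- normalize_subject(list(tr), 1)
  expect_equal(out$scale, sqrt(2.5))
  expect_equal(out$trials[[1]]$eeg, eeg / sqrt(2.5))

  # data whose channel powers already have median 1 passes through unchanged
  set.seed(3)
  eeg2 <- matrix(rnorm(64 * 400), 64)
  p <- apply(eeg2, 1, trimmed_power)
  eeg2 <- eeg2 / sqrt(stats::median(p))  # force median power to 1
  tr2 <- make_trial(eeg2, 100)
  out2 <- normalize_subject(list(tr2), 1)
  expect_equal(out2$trials[[1]]$eeg, eeg2, tolerance = 1e-9)

  # self-consistency: recomputed training powers have median 1
  p_post <- apply(out$trials[[1]]$eeg, 1, trimmed_power)
  expect_equal(stats::median(p_post), 1, tolerance = 1e-9)
})

test_that("normalization rejects mixed subjects and degenerate scales", {
  t1 <- make_trial(matrix(1, 2, 50), 100, subject = 1)
  t2 <- make_trial(matrix(1, 2, 50), 100, subject = 2)
  expect_error(normalize_subject(list(t1, t2), 1), "single subject")
  t0 <- make_trial(matrix(0, 2, 50), 100)
  expect_error(normalize_subject(list(t0), 1), "degenerate")
})

test_that("window segmentation count and length follow the 50% overlap rule", {
  tr <- make_trial(matrix(rnorm(64 * 7680), 64), 128)
  w <- segment_windows(tr, 10)
  expect_equal(length(w$label), 11)        # (7680-1280)/640 + 1
  expect_equal(w$T, 1280)
  w1 <- segment_windows(make_trial(matrix(rnorm(64 * 1280), 64), 128), 10)
  expect_equal(length(w1$label), 1)        # N == T
  w2 <- segment_windows(tr, 0.13)
  expect_equal(w2$T, 17L)                  # 130 ms at 128 Hz
  expect_error(segment_windows(make_trial(matrix(0, 64, 100), 128), 10),
               "longer than")
  expect_true(all(w$label == "left"))
})

test_that("the artifact-removal hook is identity unless given a method", {
  tr <- make_trial(matrix(rnorm(64 * 100), 64), 128)
  expect_identical(remove_artifacts(tr), tr)
  flip <- function(t) { t$eeg <- -t$eeg; t }
  out <- remove_artifacts(tr, "external", flip)
  expect_equal(out$eeg, -tr$eeg)
  expect_error(remove_artifacts(tr, "external"), "function")
})
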