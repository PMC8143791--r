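test_that("generated envelopes are nonnegative, equal-RMS, with bounded silences", {
  e <- generate_envelope(0.5, 100, seed = 1)
  expect_length(e, 50)
  expect_true(all(e >= 0))
  e1 <- generate_envelope(60, 128, seed = 2)
  e2 <- generate_envelope(60, 128, seed = 3)
  expect_equal(sqrt(mean(e1^2)), sqrt(mean(e2^2)), tolerance = 1e-6)
  r <- rle(e1 == 0)
  longest_zero <- max(c(0, r$lengths[r$values]))
  expect_lte(longest_zero, 64)             # 0.5 s at 128 Hz
  expect_error(generate_envelope(-1, 128), "positive")
  expect_error(generate_envelope(10, 0), "positive")
})

test_that("trials are bit-identical under the same configuration", {
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 2,
                      trial_duration = 4, fs_native = 512, seed = 9)
  t1 <- generate_trial(cfg, 1, 1)
  t2 <- generate_trial(cfg, 1, 1)
  expect_identical(t1, t2)
  t3 <- generate_trial(synth_config(n_subjects = 1,
                                    n_trials_per_subject = 2,
                                    trial_duration = 4, fs_native = 512,
                                    seed = 10), 1, 1)
  expect_false(identical(t1$eeg, t3$eeg))
})

band_power_asym <- function(tr, band = c(14, 32)) {
  side <- channel_side()
  X <- stats::mvfft(t(tr$eeg))
  n <- ncol(tr$eeg)
  freq <- seq(0, tr$fs - tr$fs / n, by = tr$fs / n)
  sel <- freq >= band[1] & freq <= band[2]
  p <- colSums(Mod(X[sel, , drop = FALSE])^2)
  mean(p[side == "left"]) - mean(p[side == "right"])
}

test_that("lateralized band power follows the attended ear; absent at gain 0", {
  fs <- 512
  cfg_hot <- synth_config(n_subjects = 1, n_trials_per_subject = 100,
                          trial_duration = 2, fs_native = fs,
                          lateralization_gain = 3, envelope_snr = -Inf,
                          seed = 21)
  hits <- 0
  for (t in 1:100) {
    tr <- generate_trial(cfg_hot, 1, t)
    d <- band_power_asym(tr)
    hit <- (d > 0) == (tr$attended_ear == "left")
    hits <- hits + hit
  }
  expect_gte(hits, 99)

  cfg_null <- synth_config(n_subjects = 1, n_trials_per_subject = 100,
                           trial_duration = 2, fs_native = fs,
                           lateralization_gain = 0, seed = 22)
  stat <- vapply(1:100, function(t) {
    tr <- generate_trial(cfg_null, 1, t)
    sign_ <- if (tr$attended_ear == "left") 1 else -1
    sign_ * band_power_asym(tr)
  }, numeric(1))
  expect_lt(abs(mean(stat)), 2 * stats::sd(stat) / sqrt(length(stat)))
})

test_that("dataset plan matches the experiment design under full defaults", {
  plan <- dataset_plan(synth_config())
  expect_equal(nrow(plan), 16 * 8)
  per_subject <- tapply(plan$duration, plan$subject, sum)
  expect_true(all(per_subject == 2880))    # 8 x 6 min = 48 min
  s1 <- plan[plan$subject == 1, ]
  expect_equal(sum(s1$attended_ear == "left"), 4)
  expect_equal(sum(s1$attended_ear == "right"), 4)
  expect_equal(s1$story, c(1, 1, 3, 3, 2, 2, 4, 4))
  expect_equal(s1$speaker, c(1, 1, 3, 3, 2, 2, 3, 3))
  # ear alternates over consecutive trials
  expect_true(all(s1$attended_ear[-1] != s1$attended_ear[-8]))
})

test_that("generated datasets have the planned size and balanced labels", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 2,
                      trial_duration = 2, fs_native = 512, seed = 4)
  ds <- generate_dataset(cfg)
  expect_length(ds$trials, 4)
  durations <- vapply(ds$trials, function(t) ncol(t$eeg) / t$fs, numeric(1))
  expect_true(all(durations == 2))
  ears <- vapply(ds$trials[1:2], function(t) t$attended_ear, character(1))
  expect_setequal(ears, c("left", "right"))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(trial_duration = 0), "trial_duration")
  expect_error(synth_config(fs_native = 50), "fs_native")
  expect_error(synth_config(fs_native = 300,
                            lateralization_band = c(100, 200)))
  expect_error(synth_config(lateralization_gain = -1))
  cfg <- synth_config(n_subjects = 1, n_trials_per_subject = 1,
                      trial_duration = 1, fs_native = 512)
  expect_error(generate_trial(cfg, 1, 2), "exceeds")
})
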