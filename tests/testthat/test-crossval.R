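test_that("the story+speaker rule yields exactly the surviving folds", {
  # the experiment's own map: stories 3 and 4 share a narrator
  folds <- make_story_speaker_folds(c("1" = 1, "2" = 2, "3" = 3, "4" = 3))
  expect_length(folds, 2)
  expect_setequal(vapply(folds, `[[`, numeric(1), "test_story"), c(1, 2))
  # all speakers distinct: every story can be held out
  expect_length(make_story_speaker_folds(c("1" = 1, "2" = 2, "3" = 3,
                                           "4" = 4)), 4)
  # a single speaker narrating everything leaves no valid fold
  expect_error(make_story_speaker_folds(c("1" = 1, "2" = 1)),
               "no valid folds")
  expect_error(make_story_speaker_folds(c("1" = 1)), "at least 2")
})

test_that("every-trial split keeps contiguous ordered segments and notes the resolution", {
  plan <- make_every_trial_split()
  expect_equal(plan$train_fraction + plan$val_fraction +
                 plan$test_fraction, 1)
  expect_equal(plan$val_fraction, 0.15)
  expect_equal(plan$test_fraction, 0.15)   # test = final 54 s of a 360 s trial
  expect_match(plan$note, "105%")
  expect_equal(0.15 * 360, 54)
  expect_error(make_every_trial_split(0.8, 0.15, 0.15))
})

test_that("leave-one-subject-out folds exclude the held-out subject", {
  folds <- make_loso_folds(1:16)
  expect_length(folds, 16)
  for (f in folds[c(1, 16)]) {
    expect_length(f$train_subjects, 15)
    expect_false(f$test_subject %in% f$train_subjects)
    expect_length(f$story_folds, 2)
  }
  expect_error(make_loso_folds(1), "at least 2")
})

test_that("fold assembly is leakage-free and windows never straddle split seams", {
  pre <- small_dataset_cnn(2)
  map <- pre$config$story_speaker_map
  folds <- make_story_speaker_folds(map)
  for (fold in folds) {
    expect_true(assert_no_leakage(fold, pre$trials, map))
  }
  fold <- folds[[1]]
  dat <- aadecode:::.subject_fold_windows(pre, 1, fold, window_seconds = 1)
  # train/test assignments never share a trial
  test_trials <- unique(dat$test$trial_id)
  train_trials <- unique(dat$train$trial_id)
  expect_length(intersect(test_trials, train_trials), 0)
  # within a trial, validation windows start strictly after training windows
  for (tid in train_trials) {
    tr_end <- max(dat$train$start_sample[dat$train$trial_id == tid]) +
      dat$train$T - 1
    va_start <- min(dat$val$start_sample[dat$val$trial_id == tid])
    expect_lt(tr_end, va_start + dat$val$T)  # ordered segments
    expect_gte(va_start, floor(0.85 * 60 * 128) + 1 - dat$val$T)
  }
})

test_that("normalization statistics depend on the fold's training assignment", {
  pre <- small_dataset_cnn(2)
  idx <- aadecode:::.subject_trials(pre, 1)
  trials <- pre$trials[idx]
  stories <- vapply(trials, function(t) t$story_id, numeric(1))
  s1 <- normalize_subject(trials, which(stories %in% c(2, 3, 4)))$scale
  s2 <- normalize_subject(trials, which(stories %in% c(1, 3, 4)))$scale
  expect_false(isTRUE(all.equal(s1, s2)))
})

test_that("experiment bookkeeping: rows per subject = folds x runs x windows", {
  pre <- small_dataset_cnn(2)
  res <- memo("exp_small", {
    run_experiment(pre, model = "cnn", scheme = "story_speaker",
                   windows = c(2, 1), n_runs = 1,
                   config = train_config(epochs = 2), seed = 5)
  })
  expect_equal(nrow(res), 2 * 2 * 2 * 1)   # subjects x folds x windows
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  smry <- summarize_results(res)
  expect_equal(nrow(smry$median), 2)
  # rerunning with the same seed reproduces the table exactly
  res2 <- run_experiment(pre, model = "cnn", scheme = "story_speaker",
                         windows = c(2, 1), n_runs = 1,
                         config = train_config(epochs = 2), seed = 5)
  expect_equal(res, res2)
})

test_that("the default window lists have 7 entries (CNN) and 6 (linear)", {
  w <- c(10, 5, 2, 1, 0.5, 0.25, 0.13)
  expect_length(w, 7)
  expect_length(w[round(w * 20) >= 0.25 * 20], 6)   # 0.13 s drops out
})

test_that("below-chance subjects can be excluded from summaries on request", {
  res <- data.frame(subject = rep(1:3, each = 2),
                    window_seconds = rep(c(1, 10), 3),
                    fold = 1, accuracy = c(80, 85, 45, 44, 70, 75))
  s_all <- summarize_results(res)
  s_ex <- summarize_results(res, exclude_below_chance = 10)
  expect_equal(sort(unique(s_ex$per_subject$subject)), c(1, 3))
  expect_gt(s_ex$median$accuracy[s_ex$median$window_seconds == 10],
            s_all$median$accuracy[s_all$median$window_seconds == 10])
})
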