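# Shared fixtures, memoized so expensive objects (filter designs, trained
# networks) are built once per test session.  All simulated data is
# generated here in code, at reduced rates and durations chosen for test
# runtime; the generator itself defaults to the full-scale experiment
# design.

.fix <- new.env()

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# CNN-band filter at a reduced native rate used throughout the tests;
# also seeded into the package's own design cache so pipeline calls that
# design implicitly (preprocess_dataset, end_to_end) reuse it
test_cnn_filter <- function(fs = 512) {
  memo(paste0("cnnfilt", fs), {
    f <- design_bandpass(cnn_bandpass_spec(fs))
    key <- paste(1, 32, fs, 0.5, sep = "_")
    assign(key, f, envir = aadecode:::.design_cache)
    f
  })
}

# the full-rate design backing the acceptance checks
native_cnn_filter <- function() {
  memo("cnnfilt8196", design_bandpass(cnn_bandpass_spec(8196)))
}

# small synthetic dataset (2 subjects x 8 x 60 s at 512 Hz), preprocessed
# for the CNN pathway; the raw native-rate dataset is transient and the
# stimuli (unused by the CNN) are dropped to keep the session's memory low
small_dataset_cnn <- function(gain, seed = 101) {
  memo(paste0("pre_g", gain, "_s", seed), {
    cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 8,
                        trial_duration = 60, fs_native = 512,
                        lateralization_gain = gain, seed = seed)
    raw <- generate_dataset(cfg)
    pre <- preprocess_dataset(raw, "cnn", filt = test_cnn_filter(512))
    rm(raw); gc(verbose = FALSE)
    pre$trials <- lapply(pre$trials, function(t) {
      t$stimulus_left <- NULL; t$stimulus_right <- NULL; t
    })
    pre
  })
}

# one full story+speaker fold fit on the strongly lateralized dataset:
# returns models, per-subject test windows, normalized continuous test
# trials (for ablation) and the pooled test accuracy
fold_fit <- function(gain, epochs = 40, seed = 7) {
  memo(paste0("fit_g", gain, "_e", epochs, "_s", seed), {
    pre <- small_dataset_cnn(gain)
    fold <- make_story_speaker_folds(pre$config$story_speaker_map)[[1]]
    subjects <- 1:2
    dat <- lapply(subjects, function(s) {
      aadecode:::.subject_fold_windows(pre, s, fold, window_seconds = 1)
    })
    train_w <- bind_windows(lapply(dat, `[[`, "train"))
    val_w <- bind_windows(lapply(dat, `[[`, "val"))
    cfg <- train_config(epochs = epochs, seed = seed)
    tm <- train_cnn(train_w, val_w, cfg)
    test_w <- bind_windows(lapply(dat, `[[`, "test"))
    acc <- evaluate_cnn(tm, test_w)$accuracy
    train_acc <- evaluate_cnn(tm, train_w)$accuracy
    # normalized continuous test trials (for band-ablation retests)
    test_trials <- unlist(lapply(subjects, function(s) {
      idx <- aadecode:::.subject_trials(pre, s)
      trials <- pre$trials[idx]
      stories <- vapply(trials, function(t) t$story_id, numeric(1))
      tr <- which(stories %in% fold$train_stories)
      te <- which(stories == fold$test_story)
      norm <- normalize_subject(trials, tr, training_fraction = 0.85)
      norm$trials[te]
    }), recursive = FALSE)
    rm(train_w, val_w, test_w, dat); gc(verbose = FALSE)
    list(model = tm, test_trials = test_trials, accuracy = acc,
         train_accuracy = train_acc,
         channel_power = fold_channel_power(pre, fold))
  })
}

fold_channel_power <- function(pre, fold) {
  idx <- aadecode:::.subject_trials(pre, 1)
  trials <- pre$trials[idx]
  stories <- vapply(trials, function(t) t$story_id, numeric(1))
  tr <- which(stories %in% fold$train_stories)
  normalize_subject(trials, tr, training_fraction = 0.85)$channel_power
}

# compact accuracy of a single quick training on a given dataset config
quick_cnn_accuracy <- function(gain, window_seconds = 1, epochs = 25,
                               duration = 30, seed = 301) {
  key <- paste0("qacc", gain, "_", window_seconds, "_", epochs, "_",
                duration)
  memo(key, {
    cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 8,
                        trial_duration = duration, fs_native = 512,
                        lateralization_gain = gain, seed = 77)
    pre <- preprocess_dataset(generate_dataset(cfg), "cnn",
                              filt = test_cnn_filter(512))
    fold <- make_story_speaker_folds(cfg$story_speaker_map)[[1]]
    dat <- lapply(1:2, function(s) {
      aadecode:::.subject_fold_windows(pre, s, fold, window_seconds)
    })
    tm <- train_cnn(bind_windows(lapply(dat, `[[`, "train")),
                    bind_windows(lapply(dat, `[[`, "val")),
                    train_config(epochs = epochs, seed = seed))
    evaluate_cnn(tm, bind_windows(lapply(dat, `[[`, "test")))$accuracy
  })
}
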