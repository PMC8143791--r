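# ---- Canonical on-disk container, conversion, manifests, WAV --------------
#
# The canonical container is a directory with one subdirectory per subject
# holding one serialized trial per file, plus a dataset-level metadata CSV:
#
#   <dir>/metadata.csv                        subject, trial, story, speaker,
#                                             attended_ear, presentation, fs
#   <dir>/subject-<s>/trial-<t>.rds           the aad_trial object
#
# (An HDF5 layout would be the conventional choice in this field; this
# package uses R's native serialization with the same logical structure.)

#' Write a dataset to the canonical container layout
#'
#' @param dataset an `aad_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_container <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (tr in dataset$trials) {
    sd <- file.path(dir, sprintf("subject-%d", tr$subject_id))
    dir.create(sd, showWarnings = FALSE)
    saveRDS(tr, file.path(sd, sprintf("trial-%d.rds", tr$trial_id)))
    meta[[length(meta) + 1L]] <- data.frame(
      subject = tr$subject_id, trial = tr$trial_id, story = tr$story_id,
      speaker = tr$speaker_id, attended_ear = tr$attended_ear,
      presentation = tr$presentation, fs = tr$fs)
  }
  utils::write.csv(do.call(rbind, meta), file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$config)) {
    saveRDS(dataset$config, file.path(dir, "config.rds"))
  }
  invisible(dir)
}

#' Read a dataset from the canonical container layout
#'
#' @param dir container directory.
#' @return an `aad_dataset`.
#' @export
read_container <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("not a container: missing metadata.csv")
  meta <- utils::read.csv(meta_path)
  trials <- lapply(seq_len(nrow(meta)), function(i) {
    readRDS(file.path(dir, sprintf("subject-%d", meta$subject[i]),
                      sprintf("trial-%d.rds", meta$trial[i])))
  })
  cfg_path <- file.path(dir, "config.rds")
  config <- if (file.exists(cfg_path)) readRDS(cfg_path) else NULL
  structure(list(trials = trials, config = config), class = "aad_dataset")
}

#' Convert raw EEG matrices plus metadata into the canonical container
#'
#' Validates channel counts and metadata columns, builds `aad_trial`
#' objects and writes the container.  Intended for importing recordings
#' held as numeric matrices (channels x samples); a channel subset may be
#' supplied when the source has more or fewer than the expected channels.
#'
#' @param eeg_list list of numeric matrices, one per metadata row.
#' @param metadata data frame with columns `subject`, `trial`, `story`,
#'   `speaker`, `attended_ear`, `presentation`.
#' @param fs sampling rate of the matrices, Hz.
#' @param dir output container directory.
#' @param n_channels expected channel count.
#' @param channel_subset optional indices selecting `n_channels` rows from
#'   each matrix.
#' @param stimuli optional list of `list(left =, right =)` waveforms or
#'   envelopes per trial.
#' @return the container directory, invisibly.
#' @export
convert_to_container <- function(eeg_list, metadata, fs, dir,
                                 n_channels = 64, channel_subset = NULL,
                                 stimuli = NULL) {
  required <- c("subject", "trial", "story", "speaker", "attended_ear",
                "presentation")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(eeg_list) != nrow(metadata)) {
    stop("metadata/trial mismatch: ", length(eeg_list), " EEG matrices vs ",
         nrow(metadata), " metadata rows")
  }
  trials <- lapply(seq_along(eeg_list), function(i) {
    x <- eeg_list[[i]]
    if (!is.null(channel_subset)) {
      x <- x[channel_subset, , drop = FALSE]
    }
    if (nrow(x) != n_channels) {
      stop("trial ", i, " has ", nrow(x), " channels (expected ",
           n_channels, "); supply `channel_subset`")
    }
    structure(list(
      eeg = x, fs = fs,
      subject_id = metadata$subject[i], trial_id = metadata$trial[i],
      story_id = metadata$story[i], speaker_id = metadata$speaker[i],
      attended_ear = as.character(metadata$attended_ear[i]),
      presentation = as.character(metadata$presentation[i]),
      stimulus_left = if (!is.null(stimuli)) stimuli[[i]]$left,
      stimulus_right = if (!is.null(stimuli)) stimuli[[i]]$right,
      fs_stimulus = fs
    ), class = "aad_trial")
  })
  write_container(structure(list(trials = trials, config = NULL),
                            class = "aad_dataset"), dir)
}

#' Read a PCM RIFF/WAVE file
#'
#' Minimal reader for uncompressed 16- or 32-bit PCM WAV (mono or averaged
#' to mono), sufficient for importing stimulus audio.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fs <- NULL; bits <- NULL; n_ch <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, 2, endian = "little")
      if (fmt[1] != 1) stop("only uncompressed PCM is supported")
      n_ch <- fmt[2]
      fs <- readBin(con, integer(), 1, 4, endian = "little")
      invisible(readBin(con, integer(), 1, 4, endian = "little"))
      invisible(readBin(con, integer(), 1, 2, endian = "little"))
      bits <- readBin(con, integer(), 1, 2, endian = "little")
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      bytes <- bits / 8
      data <- readBin(con, integer(), size / bytes, bytes,
                      signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(data)) stop("no data chunk found")
  x <- data / 2^(bits - 1)
  if (n_ch > 1) {
    x <- colMeans(matrix(x, n_ch))
  }
  list(samples = x, fs = fs)
}

#' Write a run manifest next to pipeline outputs
#'
#' Records the configuration snapshot, package version, seeds, per-stage
#' timings and warnings as JSON so every output is reproducible from its
#' manifest.
#'
#' @param path output file (JSON).
#' @param config configuration list (serialized as-is).
#' @param seeds named list/vector of seeds used.
#' @param timings named numeric vector of per-stage wall times (seconds).
#' @param warnings character vector of notes (e.g. the 75/15/15 split
#'   resolution).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list(),
                           timings = numeric(0), warnings = character(0)) {
  manifest <- list(
    package = "aadecode",
    version = as.character(utils::packageVersion("aadecode")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds,
    timings = as.list(timings),
    warnings = warnings)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' Simulate (or load) a dataset, preprocess it for the requested model,
#' run the cross-validated experiment, compute per-subject MESDs and write
#' results plus a manifest.
#'
#' @param config a [synth_config()] describing the simulation, or a
#'   container directory to load.
#' @param out_dir output directory.
#' @param model,scheme,windows,n_runs,train_cfg passed to
#'   [run_experiment()].
#' @param seed experiment seed.
#' @return list with `results` (results table), `mesd` (per-subject MESD),
#'   `manifest` (path).
#' @export
end_to_end <- function(config, out_dir, model = "cnn",
                       scheme = "story_speaker", windows = c(10, 1),
                       n_runs = 1, train_cfg = train_config(), seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() Sys.time()
  t0 <- tic()
  dataset <- if (inherits(config, "synth_config")) {
    generate_dataset(config)
  } else {
    read_container(config)
  }
  timings["data"] <- as.numeric(Sys.time() - t0, units = "secs")
  t0 <- tic()
  pre <- preprocess_dataset(dataset, pathway = model)
  timings["preprocess"] <- as.numeric(Sys.time() - t0, units = "secs")
  t0 <- tic()
  results <- run_experiment(pre, model = model, scheme = scheme,
                            windows = windows, n_runs = n_runs,
                            config = train_cfg, seed = seed)
  timings["experiment"] <- as.numeric(Sys.time() - t0, units = "secs")
  utils::write.csv(results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  mesd_df <- mesd_by_subject(results)
  utils::write.csv(mesd_df, file.path(out_dir, "mesd.csv"),
                   row.names = FALSE)
  notes <- if (scheme == "every_trial") make_every_trial_split()$note else
    character(0)
  man <- write_manifest(
    file.path(out_dir, "manifest.json"),
    config = if (inherits(config, "synth_config"))
      unclass(config) else list(container = config),
    seeds = list(experiment = seed),
    timings = timings, warnings = notes)
  list(results = results, mesd = mesd_df, manifest = man)
}
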