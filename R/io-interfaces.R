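# File formats and the command-line surface: WAV read/write, DEAP-layout
# subject files, native dataset directories, run configs and run directories.

# ---- WAV --------------------------------------------------------------------

#' Read a WAV file as a mono audio track
#'
#' Supports PCM 8/16/24/32-bit and IEEE float 32/64-bit encodings.
#' Multi-channel files are mixed to mono by channel averaging; no resampling
#' is performed (see [resample_track()]).
#'
#' @param path WAV file path.
#' @return an [audio_track()] at the file's native rate.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    abort_museeg(sprintf("no such file: '%s'", path), "museeg_error_io")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort_museeg(sprintf("'%s' is not a RIFF/WAVE file", path),
                 "museeg_error_bad_wav")
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1L, 2L, signed = FALSE,
                         endian = "little"),
        channels = readBin(con, "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        byte_rate = readBin(con, "integer", 1L, 4L, endian = "little"),
        block_align = readBin(con, "integer", 1L, 2L, signed = FALSE,
                              endian = "little"),
        bits = readBin(con, "integer", 1L, 2L, signed = FALSE,
                       endian = "little"))
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) {
        abort_museeg("malformed WAV: data chunk before fmt chunk",
                     "museeg_error_bad_wav")
      }
      samples <- read_wav_data(con, size, fmt, path)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(samples)) {
    abort_museeg(sprintf("no data chunk found in '%s'", path),
                 "museeg_error_bad_wav")
  }
  x <- if (fmt$channels > 1L) {
    colMeans(matrix(samples, nrow = fmt$channels))
  } else {
    samples
  }
  audio_track(x, fmt$rate, tools::file_path_sans_ext(basename(path)))
}

read_wav_data <- function(con, size, fmt, path) {
  n <- size %/% (fmt$bits %/% 8L)
  if (fmt$format == 1L) {        # integer PCM
    switch(as.character(fmt$bits),
      "8" = (readBin(con, "integer", n, 1L, signed = FALSE) - 128) / 128,
      "16" = readBin(con, "integer", n, 2L, endian = "little") / 32768,
      "24" = {
        raw <- readBin(con, "raw", size)
        b <- matrix(as.integer(raw), nrow = 3L)
        v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
        ifelse(v >= 8388608, v - 16777216, v) / 8388608
      },
      "32" = readBin(con, "integer", n, 4L, endian = "little") / 2147483648,
      abort_museeg(sprintf("unsupported PCM bit depth %d in '%s'",
                           fmt$bits, path), "museeg_error_bad_wav"))
  } else if (fmt$format == 3L) { # IEEE float
    switch(as.character(fmt$bits),
      "32" = readBin(con, "numeric", n, 4L, endian = "little"),
      "64" = readBin(con, "numeric", n, 8L, endian = "little"),
      abort_museeg(sprintf("unsupported float bit depth %d in '%s'",
                           fmt$bits, path), "museeg_error_bad_wav"))
  } else {
    abort_museeg(sprintf("unsupported WAV encoding (format tag %d) in '%s'",
                         fmt$format, path), "museeg_error_bad_wav")
  }
}

#' Write an audio track as WAV
#'
#' @param track an [audio_track()].
#' @param path output file.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(track, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(track, "audio_track"))
  format <- match.arg(format)
  x <- track$samples
  bits <- if (format == "pcm16") 16L else 32L
  tag <- if (format == "pcm16") 1L else 3L
  n_bytes <- length(x) * (bits %/% 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, 2L, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, 4L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + n_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(tag); w16(1L); w32(as.integer(round(track$sample_rate)))
  w32(as.integer(round(track$sample_rate)) * (bits %/% 8L))
  w16(bits %/% 8L); w16(bits)
  writeChar("data", con, eos = NULL); w32(n_bytes)
  if (format == "pcm16") {
    q <- pmin(pmax(round(x * 32768), -32768), 32767)  # symmetric with read
    writeBin(as.integer(q), con, 2L, endian = "little")
  } else {
    writeBin(x, con, 4L, endian = "little")
  }
  invisible(path)
}

# ---- DEAP-layout subject files ---------------------------------------------

#' Read one subject file in the DEAP preprocessed layout
#'
#' Expects a serialized record (RDS) with `data` shaped
#' `(n_trials, >= 32 channels, samples)` and `labels` shaped
#' `(n_trials, >= 2)`; the first 32 channels are EEG and the first two label
#' columns are (valence, arousal). The original release stores Python
#' pickles with the same keys and shapes; convert those to RDS once (e.g.
#' via any array-preserving interchange format) before reading. The 3 s
#' baseline prefix is removed, leaving 7680 samples per 60 s trial at
#' 128 Hz.
#'
#' @param path subject file.
#' @param baseline_s baseline prefix to strip, in seconds.
#' @return list with one element per trial: `eeg` (an [eeg_trial()]),
#'   `valence`, `arousal`, and `labels` (the full label row).
#' @export
read_deap_subject <- function(path, baseline_s = 3) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort_museeg(sprintf("cannot parse '%s' as a DEAP-layout subject file: %s",
                         path, conditionMessage(e)),
                 "museeg_error_deap_parse")
  })
  if (!is.list(obj) || !all(c("data", "labels") %in% names(obj))) {
    abort_museeg(sprintf("'%s' must contain keys 'data' and 'labels'", path),
                 "museeg_error_deap_parse")
  }
  d <- dim(obj$data)
  if (length(d) != 3L || d[2L] < 32L) {
    abort_museeg(
      sprintf("'data' must be a 3-d array (trials x >=32 channels x samples), got shape (%s)",
              paste(d, collapse = ", ")),
      "museeg_error_deap_parse")
  }
  labels <- as.matrix(obj$labels)
  if (nrow(labels) != d[1L] || ncol(labels) < 2L) {
    abort_museeg("'labels' must have one row per trial and at least 2 columns",
                 "museeg_error_deap_parse")
  }
  fs <- 128
  n_base <- as.integer(round(baseline_s * fs))
  if (d[3L] <= n_base) {
    abort_museeg(sprintf("trials of %d samples are shorter than the %d-sample baseline",
                         d[3L], n_base),
                 "museeg_error_deap_parse")
  }
  subject_id <- tools::file_path_sans_ext(basename(path))
  lapply(seq_len(d[1L]), function(k) {
    eeg <- eeg_trial(obj$data[k, 1:32, (n_base + 1L):d[3L]],
                     sample_rate = fs, channel_names = deap_channels(),
                     trial_id = sprintf("%s_t%02d", subject_id, k),
                     subject_id = subject_id)
    list(eeg = eeg, valence = unname(labels[k, 1L]),
         arousal = unname(labels[k, 2L]), labels = labels[k, ])
  })
}

# ---- native dataset directories --------------------------------------------

#' Write a dataset as a native directory
#'
#' One 16-bit PCM WAV and one EEG CSV (rows = channels, first column the
#' channel name) per trial, plus a `labels.csv` manifest.
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_native_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "trial_dataset"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) {
    abort_museeg(sprintf("cannot create directory '%s'", dir),
                 "museeg_error_unwritable")
  }
  rows <- lapply(dataset, function(ex) {
    wav_file <- paste0(ex$trial_id, ".wav")
    eeg_file <- paste0(ex$trial_id, "_eeg.csv")
    write_wav(trial_audio(ex), file.path(dir, wav_file))
    eeg <- trial_eeg(ex)
    df <- data.frame(channel = eeg$channel_names, eeg$data,
                     check.names = FALSE)
    write.csv(df, file.path(dir, eeg_file), row.names = FALSE)
    data.frame(subject_id = ex$subject_id, trial_id = ex$trial_id,
               valence = ex$valence, arousal = ex$arousal,
               sample_rate = eeg$sample_rate,
               audio_file = wav_file, eeg_file = eeg_file)
  })
  write.csv(do.call(rbind, rows), file.path(dir, "labels.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a native dataset directory
#'
#' @param dir directory written by [write_native_dataset()].
#' @return a `trial_dataset` with materialized audio and EEG.
#' @export
read_native_dataset <- function(dir) {
  manifest_path <- file.path(dir, "labels.csv")
  if (!file.exists(manifest_path)) {
    abort_museeg(sprintf("no labels.csv manifest in '%s'", dir),
                 "museeg_error_io")
  }
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  examples <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    eeg_df <- read.csv(file.path(dir, row$eeg_file), check.names = FALSE)
    eeg <- eeg_trial(as.matrix(eeg_df[, -1L, drop = FALSE]),
                     sample_rate = row$sample_rate,
                     channel_names = eeg_df$channel,
                     trial_id = row$trial_id, subject_id = row$subject_id)
    structure(
      list(subject_id = row$subject_id, trial_id = row$trial_id,
           valence = row$valence, arousal = row$arousal,
           valence_latent = NA_real_, arousal_latent = NA_real_,
           planted_beta_alpha = NA_real_, audio_seed = NA_integer_,
           eeg_seed = NA_integer_,
           audio = read_wav(file.path(dir, row$audio_file)), eeg = eeg,
           gen = NULL),
      class = "trial_example")
  })
  structure(examples, class = "trial_dataset", config = NULL)
}

# ---- run configuration ------------------------------------------------------

default_training_control <- function() {
  list(lr = 2e-3, batch_size = 16L, max_epochs = 250L, patience = 20L)
}

#' Load and validate a run configuration (YAML)
#'
#' Sections: `synthetic` (arguments of [synthetic_config()]), `model`
#' (arguments of [fusion_config()]), `training` (`lr`, `batch_size`,
#' `max_epochs`, `patience`), `seed`, and `paths` (`data_dir`, `out_dir`).
#' Unknown keys anywhere are rejected with a named error.
#'
#' @param path YAML file.
#' @return object of class `run_config` with constructed `synthetic` and
#'   `model` configs, merged `training` control, `seed`, `paths`, and the
#'   raw list (`raw`) for lossless re-serialization.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(given, allowed)
    if (length(bad)) {
      abort_museeg(sprintf("unknown key(s) in %s: %s", where,
                           paste(bad, collapse = ", ")),
                   "museeg_error_unknown_key", keys = bad)
    }
  }
  check_keys(names(raw), c("synthetic", "model", "training", "seed", "paths"),
             "run config")
  check_keys(names(raw$synthetic), names(formals(synthetic_config)),
             "section 'synthetic'")
  check_keys(names(raw$model), names(formals(fusion_config)),
             "section 'model'")
  check_keys(names(raw$training), names(default_training_control()),
             "section 'training'")
  check_keys(names(raw$paths), c("data_dir", "out_dir"), "section 'paths'")
  structure(
    list(synthetic = do.call(synthetic_config, raw$synthetic %||% list()),
         model = do.call(fusion_config, raw$model %||% list()),
         training = modifyList(default_training_control(),
                               raw$training %||% list()),
         seed = as.integer(raw$seed %||% 1L),
         paths = raw$paths %||% list(),
         raw = raw),
    class = "run_config"
  )
}

#' Save a run configuration snapshot
#'
#' @param config a `run_config` (its raw list is written, so
#'   [load_run_config()] round-trips exactly).
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

# ---- run directories --------------------------------------------------------

write_run_dir <- function(run, dir, config_raw = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) {
    abort_museeg(sprintf("cannot create run directory '%s'", dir),
                 "museeg_error_unwritable")
  }
  if (!is.null(config_raw)) {
    yaml::write_yaml(config_raw, file.path(dir, "config.yaml"))
  }
  writeLines(as.character(run$seed), file.path(dir, "seed.txt"))
  write.csv(run$fit$history, file.path(dir, "history.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(unclass(run$metrics), unclass),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  truth <- run$tensors$labels[run$split$test_ids, , drop = FALSE]
  write.csv(
    data.frame(trial = run$split$test_ids,
               pred_valence = run$predictions[, 1L],
               pred_arousal = run$predictions[, 2L],
               true_valence = truth[, 1L], true_arousal = truth[, 2L]),
    file.path(dir, "predictions.csv"), row.names = FALSE)
  saveRDS(run, file.path(dir, "run.rds"))
  invisible(dir)
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "museeg <command> [--flag value ...]",
    "",
    "commands:",
    "  generate       --out DIR [--config CFG.yaml] [--format native|deap]",
    "  extract-audio  --in TRACK.wav --out FEATURES.csv [--window 1.0] [--overlap 0.5]",
    "  extract-eeg    --in SUBJECT.rds --out FEATURES.csv",
    "  train          --data DIR --out RUNDIR [--config CFG.yaml] [--seed N]",
    "  ablate         --data DIR --out RUNDIR [--config CFG.yaml] [--seed N]",
    "  evaluate       --run RUNDIR",
    "  attribute      --run RUNDIR [--method gradient_input|occlusion]",
    "  help",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      abort_museeg(sprintf("unexpected argument '%s'", a), "museeg_error_cli")
    }
    nm <- substring(a, 3L)
    if (nm == "help") {
      flags$help <- TRUE
      i <- i + 1L
    } else {
      if (i + 1L > length(args)) {
        abort_museeg(sprintf("flag --%s needs a value", nm),
                     "museeg_error_cli")
      }
      flags[[nm]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

require_flag <- function(flags, name) {
  if (is.null(flags[[name]])) {
    abort_museeg(sprintf("missing required flag --%s", name),
                 "museeg_error_cli", flag = name)
  }
  flags[[name]]
}

cli_load_config <- function(flags) {
  if (!is.null(flags$config)) load_run_config(flags$config) else
    structure(list(synthetic = synthetic_config(), model = fusion_config(),
                   training = default_training_control(), seed = 1L,
                   paths = list(), raw = NULL),
              class = "run_config")
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; see `cli_usage` output
#' (`museeg help`) for the subcommands. Installed alongside the package as
#' `system.file("cli", "museeg.R", package = "museeg")`, runnable with
#' `Rscript`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
cli_entry <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L || args[1L] %in% c("help", "--help", "-h")) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    cmd <- args[1L]
    flags <- parse_cli_flags(args[-1L])
    if (isTRUE(flags$help)) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    switch(cmd,
      "generate" = {
        out <- require_flag(flags, "out")
        cfg <- cli_load_config(flags)
        fmt <- flags$format %||% "native"
        ds <- generate_dataset(cfg$synthetic)
        if (fmt == "native") {
          write_native_dataset(ds, out)
        } else if (fmt == "deap") {
          generate_deap_format_fixture(ds, out)
        } else {
          abort_museeg(sprintf("unknown format '%s'", fmt),
                       "museeg_error_cli")
        }
        message(sprintf("wrote %d trials to %s (%s format)",
                        length(ds), out, fmt))
        0L
      },
      "extract-audio" = {
        infile <- require_flag(flags, "in")
        out <- require_flag(flags, "out")
        tr <- read_wav(infile)
        tf <- track_features(tr,
                             window_s = as.numeric(flags$window %||% 1),
                             overlap = as.numeric(flags$overlap %||% 0.5))
        write_timbre_csv(tf, out)
        message(sprintf("wrote %d windows x 5 features to %s",
                        nrow(tf$values), out))
        0L
      },
      "extract-eeg" = {
        infile <- require_flag(flags, "in")
        out <- require_flag(flags, "out")
        trials <- read_deap_subject(infile)
        dfs <- lapply(trials, function(tr) {
          psd <- compute_psd(bandpass_filter(tr$eeg))
          bpf <- band_peak_features(psd)
          data.frame(subject_id = tr$eeg$subject_id,
                     trial_id = tr$eeg$trial_id,
                     as.data.frame(bpf))
        })
        write.csv(do.call(rbind, dfs), out, row.names = FALSE)
        message(sprintf("wrote band-peak features for %d trials to %s",
                        length(trials), out))
        0L
      },
      "train" = ,
      "ablate" = {
        data_dir <- require_flag(flags, "data")
        out <- require_flag(flags, "out")
        cfg <- cli_load_config(flags)
        seed <- as.integer(flags$seed %||% cfg$seed)
        ds <- read_native_dataset(data_dir)
        tc <- cfg$training
        if (cmd == "train") {
          run <- run_experiment(ds, cfg$model, seed = seed, lr = tc$lr,
                                batch_size = tc$batch_size,
                                max_epochs = tc$max_epochs,
                                patience = tc$patience)
          write_run_dir(run, out, cfg$raw)
          print(run$metrics)
        } else {
          ab <- run_ablation(ds, cfg$model, seed = seed, lr = tc$lr,
                             batch_size = tc$batch_size,
                             max_epochs = tc$max_epochs,
                             patience = tc$patience)
          write_run_dir(ab$full, file.path(out, "full"), cfg$raw)
          write_run_dir(ab$ablation, file.path(out, "ablation"), cfg$raw)
          print(ab)
        }
        0L
      },
      "evaluate" = {
        rundir <- require_flag(flags, "run")
        run <- readRDS(file.path(rundir, "run.rds"))
        print(run$metrics)
        0L
      },
      "attribute" = {
        rundir <- require_flag(flags, "run")
        run <- readRDS(file.path(rundir, "run.rds"))
        rep <- attribute_channels(run,
                                  method = flags$method %||% "gradient_input")
        jsonlite::write_json(
          list(method = rep$method,
               channel_scores = as.list(rep$channel_scores),
               ranking = rep$ranking),
          file.path(rundir, "attribution.json"), auto_unbox = TRUE,
          digits = NA)
        print(rep)
        0L
      },
      {
        abort_museeg(sprintf("unknown command '%s'", cmd),
                     "museeg_error_cli")
      })
  }, museeg_error = function(e) {
    message("museeg: ", conditionMessage(e))
    message(cli_usage())
    2L
  }, error = function(e) {
    message("museeg: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
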