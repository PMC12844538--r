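# DEAP-shaped synthetic multimodal datasets with known generative links.
#
# Each trial draws latent valence and arousal uniformly on [1, 9]. Audio is
# a harmonic tone stack whose spectral tilt (hence spectral centroid) rises
# monotonically with valence; EEG is band-limited oscillations plus 1/f
# background noise, with the beta/alpha amplitude ratio on the designated
# signal channels rising monotonically (log-linearly) with arousal. Ratings
# are the latents plus Gaussian rating noise, clipped to [1, 9]. Valence is
# planted predominantly in audio and arousal exclusively in EEG so the
# EEG-off ablation has a guaranteed direction.
#
# Waveforms and EEG matrices are synthesized on demand from per-trial seeds
# (see trial_audio()/trial_eeg()); a full 32 x 40 dataset therefore fits in
# memory and the same master seed always reproduces identical signals.

#' Configuration of the synthetic dataset generator
#'
#' Defaults emulate the DEAP layout: 32 subjects x 40 trials, 60 s trials,
#' 32 EEG channels at 128 Hz, audio at 22050 Hz, ratings on `[1, 9]`.
#'
#' @param n_subjects,n_trials dataset layout (trials per subject).
#' @param trial_seconds trial duration (s).
#' @param eeg_rate,n_channels EEG sampling rate (Hz) and channel count.
#' @param audio_rate audio sampling rate (Hz).
#' @param seed master seed; the whole dataset is a deterministic function
#'   of it.
#' @param valence_link strength of the audio spectral-centroid link to
#'   valence (1 = full designed range, 0 = no link).
#' @param arousal_link strength of the EEG beta/alpha link to arousal.
#' @param noise_sd standard deviation of the rating noise added to the
#'   latents (rating units).
#' @param signal_channels channels carrying the arousal signal.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 32L, n_trials = 40L,
                             trial_seconds = 60, eeg_rate = 128,
                             n_channels = 32L, audio_rate = 22050,
                             seed = 1L, valence_link = 1,
                             arousal_link = 1, noise_sd = 0.5,
                             signal_channels = c("Fp1", "Fp2", "P3", "P4")) {
  if (!is_count(n_subjects) || !is_count(n_trials) || !is_count(n_channels)) {
    abort_museeg("subject/trial/channel counts must be positive integers",
                 "museeg_error_bad_config")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    abort_museeg("noise_sd must be non-negative", "museeg_error_bad_config")
  }
  channel_names <- if (n_channels == 32L) deap_channels() else
    sprintf("ch%02d", seq_len(n_channels))
  unknown <- setdiff(signal_channels, channel_names)
  if (length(unknown)) {
    abort_museeg(paste("signal_channels not in the channel set:",
                       paste(unknown, collapse = ", ")),
                 "museeg_error_bad_config")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
         trial_seconds = trial_seconds, eeg_rate = eeg_rate,
         n_channels = as.integer(n_channels), audio_rate = audio_rate,
         seed = as.integer(seed), valence_link = valence_link,
         arousal_link = arousal_link, noise_sd = noise_sd,
         signal_channels = signal_channels, channel_names = channel_names),
    class = "synthetic_config"
  )
}

# Harmonic-stack audio: amplitude of harmonic h is h^(-gamma) with gamma
# decreasing in valence, so spectral mass (and the centroid) shifts upward
# monotonically as valence rises.
synth_audio_waveform <- function(v_latent, seed, config, track_id) {
  u <- (v_latent - 1) / 8
  g <- min(1, max(0, u * config$valence_link))
  gamma <- max(0.3, 3 - 2.4 * g)
  n <- as.integer(round(config$trial_seconds * config$audio_rate))
  t <- (0:(n - 1L)) / config$audio_rate
  nh <- 8L
  f0 <- 220
  amps <- (1:nh)^(-gamma)
  amps <- amps / sum(amps)  # constant total tone mass across valence levels
  with_seed(seed, {
    phases <- runif(nh, 0, 2 * pi)
    x <- rnorm(n, 0, 0.005)
    for (h in seq_len(nh)) {
      x <- x + amps[h] * sin(2 * pi * f0 * h * t + phases[h])
    }
    x <- 0.9 * x / max(abs(x))
  })
  audio_track(x, config$audio_rate, track_id)
}

band_center_ranges <- function() {
  # interior sub-ranges so planted line frequencies stay clear of band edges
  cbind(lo = c(1, 4.5, 8.5, 14, 31), hi = c(3.5, 7.5, 12.5, 29, 44))
}

# Band-limited oscillations (one sinusoid per band per channel, random
# frequency and phase) plus 1/f background noise. On the signal channels the
# alpha/beta amplitudes follow an exponential link so the log beta/alpha
# power ratio is linear in arousal.
synth_eeg_matrix <- function(a_latent, seed, config, trial_id, subject_id) {
  u <- (a_latent - 1) / 8
  g <- min(1, max(0, u * config$arousal_link))
  fs <- config$eeg_rate
  n <- as.integer(round(config$trial_seconds * fs))
  nch <- config$n_channels
  t <- (0:(n - 1L)) / fs
  rng <- band_center_ranges()
  nb <- nrow(rng)
  base_amp <- c(delta = 8, theta = 6, alpha = 5, beta = 2.2, gamma = 1.5)
  is_sig <- config$channel_names %in% config$signal_channels
  with_seed(seed, {
    freqs <- matrix(runif(nch * nb, rng[, "lo"], rng[, "hi"]), nb, nch)
    phases <- matrix(runif(nch * nb, 0, 2 * pi), nb, nch)
    amps <- matrix(base_amp, nb, nch)
    amps[3L, is_sig] <- 5 * exp(-0.45 * g)    # alpha falls with arousal
    amps[4L, is_sig] <- 2.2 * exp(0.45 * g)   # beta rises with arousal
    S <- sin(outer(t, 2 * pi * as.vector(freqs)) +
               rep(as.vector(phases), each = n))
    S <- S * rep(as.vector(amps), each = n)
    tones <- vapply(seq_len(nch), function(c) {
      rowSums(S[, ((c - 1L) * nb + 1L):(c * nb), drop = FALSE])
    }, numeric(n))
    # 1/f noise: spectrally shaped white noise, power exponent 1
    W <- matrix(rnorm(n * nch), n, nch)
    f <- c(0:(n %/% 2L), rev(seq_len((n - 1L) %/% 2L))) * fs / n
    shape <- 1 / sqrt(pmax(f, f[2L]))
    shape[1L] <- 0
    P <- Re(stats::mvfft(stats::mvfft(W) * shape, inverse = TRUE)) / n
    P <- sweep(P, 2L, apply(P, 2L, sd), "/") * 2
    data <- t(tones + P)
  })
  eeg_trial(data, fs, config$channel_names, trial_id, subject_id)
}

#' Generate a synthetic DEAP-shaped dataset
#'
#' Returns one record per trial (`n_subjects * n_trials` in total; 1280
#' under the defaults). Each record carries the ratings, the latent values,
#' the planted beta/alpha power ratio and per-trial seeds; the audio
#' waveform and EEG matrix are synthesized on demand by [trial_audio()] and
#' [trial_eeg()], deterministically for a given master seed.
#'
#' @param config a [synthetic_config()].
#' @return list of `trial_example` objects (class `trial_dataset`), with the
#'   config attached as attribute `"config"`.
#' @examples
#' ds <- generate_dataset(synthetic_config(n_subjects = 1, n_trials = 2,
#'                                         trial_seconds = 4))
#' length(ds)
#' dim(trial_eeg(ds[[1]])$data)
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects * config$n_trials
  with_seed(config$seed, {
    v_lat <- runif(n, 1, 9)
    a_lat <- runif(n, 1, 9)
    v_lab <- pmin(pmax(v_lat + rnorm(n, 0, config$noise_sd), 1), 9)
    a_lab <- pmin(pmax(a_lat + rnorm(n, 0, config$noise_sd), 1), 9)
    audio_seeds <- sample.int(2147483646L, n)
    eeg_seeds <- sample.int(2147483646L, n)
  })
  examples <- vector("list", n)
  for (i in seq_len(n)) {
    s <- (i - 1L) %/% config$n_trials + 1L
    k <- (i - 1L) %% config$n_trials + 1L
    g <- min(1, max(0, (a_lat[i] - 1) / 8 * config$arousal_link))
    examples[[i]] <- structure(
      list(subject_id = sprintf("s%02d", s),
           trial_id = sprintf("s%02d_t%02d", s, k),
           valence = v_lab[i], arousal = a_lab[i],
           valence_latent = v_lat[i], arousal_latent = a_lat[i],
           planted_beta_alpha = (2.2 / 5)^2 * exp(1.8 * g),
           audio_seed = audio_seeds[i], eeg_seed = eeg_seeds[i],
           audio = NULL, eeg = NULL,
           gen = config),
      class = "trial_example")
  }
  structure(examples, class = "trial_dataset", config = config)
}

#' Materialize the audio of a trial example
#'
#' Returns the stored waveform when the example already carries one (e.g.
#' read from disk), otherwise synthesizes it from the example's seed.
#'
#' @param example a `trial_example`.
#' @return an [audio_track()].
#' @export
trial_audio <- function(example) {
  stopifnot(inherits(example, "trial_example"))
  if (!is.null(example$audio)) return(example$audio)
  synth_audio_waveform(example$valence_latent, example$audio_seed,
                       example$gen, example$trial_id)
}

#' Materialize the EEG of a trial example
#'
#' @param example a `trial_example`.
#' @return an [eeg_trial()].
#' @export
trial_eeg <- function(example) {
  stopifnot(inherits(example, "trial_example"))
  if (!is.null(example$eeg)) return(example$eeg)
  synth_eeg_matrix(example$arousal_latent, example$eeg_seed, example$gen,
                   example$trial_id, example$subject_id)
}

#' @export
print.trial_example <- function(x, ...) {
  cat(sprintf("<trial_example %s: valence %.2f, arousal %.2f>\n",
              x$trial_id, x$valence, x$arousal))
  invisible(x)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<trial_dataset: %d trials (%d subjects x %d), seed %d>\n",
              length(x), cfg$n_subjects, cfg$n_trials, cfg$seed))
  invisible(x)
}

#' Write a dataset in the DEAP preprocessed layout
#'
#' One serialized record per subject (`s01.rds`, ...), each a list with
#' `data` shaped `(n_trials, 40, samples)` — 32 EEG channels plus 8
#' white-noise placeholder peripheral channels, a 3 s baseline prefix before
#' the trial proper — and `labels` shaped `(n_trials, 4)` with columns
#' (valence, arousal, dominance, liking); dominance and liking are random
#' placeholders. [read_deap_subject()] round-trips these files.
#'
#' @param dataset a `trial_dataset` from [generate_dataset()] (or a
#'   [synthetic_config()], which is generated first).
#' @param out_dir output directory (created if needed).
#' @param baseline_s baseline prefix length in seconds.
#' @return character vector of file paths, invisibly.
#' @export
generate_deap_format_fixture <- function(dataset, out_dir, baseline_s = 3) {
  if (inherits(dataset, "synthetic_config")) {
    dataset <- generate_dataset(dataset)
  }
  stopifnot(inherits(dataset, "trial_dataset"))
  config <- attr(dataset, "config")
  ok <- dir.exists(out_dir) ||
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L) {
    abort_museeg(sprintf("cannot write to directory '%s'", out_dir),
                 "museeg_error_unwritable")
  }
  fs <- config$eeg_rate
  n_base <- as.integer(round(baseline_s * fs))
  n_trial <- as.integer(round(config$trial_seconds * fs))
  n_chan_file <- 40L
  paths <- character(config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    arr <- array(0, c(config$n_trials, n_chan_file, n_base + n_trial))
    labels <- matrix(NA_real_, config$n_trials, 4L,
                     dimnames = list(NULL, c("valence", "arousal",
                                             "dominance", "liking")))
    for (k in seq_len(config$n_trials)) {
      ex <- dataset[[(s - 1L) * config$n_trials + k]]
      eeg <- trial_eeg(ex)
      with_seed(derive_seed(ex$eeg_seed, 17L), {
        arr[k, seq_len(config$n_channels), seq_len(n_base)] <-
          matrix(rnorm(config$n_channels * n_base, 0, 2),
                 config$n_channels, n_base)
        arr[k, (config$n_channels + 1L):n_chan_file, ] <-
          matrix(rnorm((n_chan_file - config$n_channels) *
                         (n_base + n_trial)),
                 n_chan_file - config$n_channels, n_base + n_trial)
        labels[k, ] <- c(ex$valence, ex$arousal, runif(1, 1, 9),
                         runif(1, 1, 9))
      })
      arr[k, seq_len(config$n_channels), (n_base + 1L):(n_base + n_trial)] <-
        eeg$data
    }
    paths[s] <- file.path(out_dir, sprintf("s%02d.rds", s))
    saveRDS(list(data = arr, labels = labels), paths[s])
  }
  invisible(paths)
}
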