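# EEG containers, band-limiting, PSD estimation and band-peak features.
#
# Trials follow the DEAP preprocessed layout: 32 channels at 128 Hz, 60 s
# (7680 samples). The pipeline band-limits to 0.5-45 Hz with a zero-phase
# Butterworth cascade, estimates the per-channel power spectral density by
# Welch-averaged FFT, and keeps, for each of the five canonical bands, the
# frequency of the PSD maximum and the maximum itself (dominant oscillatory
# activity), giving 32 channels x 5 bands x 2 = 320 features per trial.

#' DEAP 32-electrode channel names
#'
#' The documented channel ordering of the DEAP preprocessed release
#' (10-20 system, Geneva order).
#'
#' @return character vector of 32 electrode labels.
#' @export
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "C4",
    "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2", "Cz")
}

#' Canonical EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 and low gamma 30-45 Hz;
#' the five bands tile `[0.5, 45]` without gaps.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 13, 30),
             hi = c(4, 8, 13, 30, 45))
}

#' Construct an EEG trial
#'
#' @param data numeric matrix, channels x samples.
#' @param sample_rate sampling rate in Hz (128 for DEAP).
#' @param channel_names electrode labels, one per row of `data`.
#' @param trial_id,subject_id identifiers.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, sample_rate = 128,
                      channel_names = NULL,
                      trial_id = "trial", subject_id = "subject") {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_museeg("EEG data must be a numeric channels x samples matrix",
                 "museeg_error_bad_eeg")
  }
  if (!all(is.finite(data))) {
    abort_museeg("EEG data must be finite", "museeg_error_nonfinite")
  }
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 32L) deap_channels() else
      sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    abort_museeg("channel_names must match the number of rows of data",
                 "museeg_error_bad_eeg")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, sample_rate = as.numeric(sample_rate),
         channel_names = as.character(channel_names),
         trial_id = as.character(trial_id),
         subject_id = as.character(subject_id)),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial '%s/%s': %d channels x %d samples @ %g Hz>\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data),
              x$sample_rate))
  invisible(x)
}

#' Zero-phase band-limiting of an EEG trial
#'
#' Applies a cascade of 4th-order Butterworth high-pass (at `lo`) and
#' low-pass (at `hi`) filters, each run forward-backward
#' ([signal::filtfilt()]) so the net filter has zero phase. The cascade is
#' numerically better behaved than a single very wide band-pass prototype at
#' this sampling rate.
#'
#' @param trial an [eeg_trial()].
#' @param lo,hi band edges in Hz; `hi` must lie below the Nyquist frequency.
#' @return a band-limited [eeg_trial()] with identical shape and metadata.
#' @export
bandpass_filter <- function(trial, lo = 0.5, hi = 45) {
  stopifnot(inherits(trial, "eeg_trial"))
  nyq <- trial$sample_rate / 2
  if (!(lo > 0 && lo < hi)) {
    abort_museeg("band edges must satisfy 0 < lo < hi",
                 "museeg_error_bad_band")
  }
  if (hi >= nyq) {
    abort_museeg(
      sprintf("upper edge %g Hz must lie below the Nyquist frequency %g Hz",
              hi, nyq),
      "museeg_error_band_above_nyquist")
  }
  hp <- signal::butter(4, lo / nyq, type = "high")
  lp <- signal::butter(4, hi / nyq, type = "low")
  out <- t(apply(trial$data, 1L, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  eeg_trial(out, trial$sample_rate, trial$channel_names,
            trial$trial_id, trial$subject_id)
}

#' Per-channel power spectral density
#'
#' Welch estimate by default: Hann-tapered 2 s (256-sample at 128 Hz)
#' segments with 50% overlap, periodograms averaged per channel; variance
#' reduction keeps band peaks stable. `method = "periodogram"` uses one
#' Hann-tapered full-length FFT instead. One-sided density scaling, so the
#' integral of the PSD over frequency approximates the signal variance.
#'
#' @param trial an [eeg_trial()].
#' @param method `"welch"` (default) or `"periodogram"`.
#' @param segment_s Welch segment length in seconds.
#' @param overlap fractional segment overlap.
#' @return An object of class `psd_spectrum`: list with `freqs` (Hz),
#'   `power` (channels x frequencies, power per Hz) and `channel_names`.
#' @export
compute_psd <- function(trial, method = c("welch", "periodogram"),
                        segment_s = 2, overlap = 0.5) {
  stopifnot(inherits(trial, "eeg_trial"))
  method <- match.arg(method)
  fs <- trial$sample_rate
  n <- ncol(trial$data)
  nper <- if (method == "welch") as.integer(round(segment_s * fs)) else n
  if (n < nper) {
    abort_museeg(
      sprintf("trial too short for PSD: need at least %d samples, got %d",
              nper, n),
      "museeg_error_trial_too_short")
  }
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  starts <- if (method == "welch") seq(1L, n - nper + 1L, by = step) else 1L
  w <- hann_window(nper)
  U <- sum(w^2)
  K <- nper %/% 2L + 1L
  scale <- 2 / (fs * U)
  pow <- matrix(0, nrow(trial$data), K)
  for (c in seq_len(nrow(trial$data))) {
    seg <- vapply(starts, function(s) trial$data[c, s:(s + nper - 1L)],
                  numeric(nper))
    X <- stats::mvfft(seg * w)
    P <- rowMeans(Mod(X[seq_len(K), , drop = FALSE])^2) * scale
    P[1L] <- P[1L] / 2                     # DC is not doubled
    if (nper %% 2L == 0L) P[K] <- P[K] / 2 # nor the Nyquist bin
    pow[c, ] <- P
  }
  structure(
    list(freqs = (0:(K - 1L)) * fs / nper, power = pow,
         channel_names = trial$channel_names,
         sample_rate = fs, method = method),
    class = "psd_spectrum"
  )
}

#' Band-peak features from a PSD
#'
#' For every channel and band, the grid frequency with the highest PSD value
#' inside `[lo, hi]` and that PSD value itself — the dominant oscillatory
#' activity per band. Ties are broken toward the lower frequency.
#'
#' @param psd a `psd_spectrum` from [compute_psd()].
#' @param bands a data.frame like [eeg_bands()].
#' @return An object of class `band_peak_features`: an array
#'   (channels x bands x 2), last axis `(peak_freq, peak_power)`.
#' @export
band_peak_features <- function(psd, bands = eeg_bands()) {
  stopifnot(inherits(psd, "psd_spectrum"))
  nch <- nrow(psd$power)
  nb <- nrow(bands)
  out <- array(NA_real_, c(nch, nb, 2L),
               dimnames = list(psd$channel_names, bands$name,
                               c("peak_freq", "peak_power")))
  for (b in seq_len(nb)) {
    idx <- which(psd$freqs >= bands$lo[b] & psd$freqs <= bands$hi[b])
    if (length(idx) == 0L) {
      abort_museeg(
        sprintf("band '%s' [%g, %g] Hz contains no grid frequency",
                bands$name[b], bands$lo[b], bands$hi[b]),
        "museeg_error_band_outside_grid")
    }
    sub <- psd$power[, idx, drop = FALSE]
    imax <- max.col(sub, ties.method = "first")  # first = lowest frequency
    out[, b, 1L] <- psd$freqs[idx[imax]]
    out[, b, 2L] <- sub[cbind(seq_len(nch), imax)]
  }
  structure(list(values = out, bands = bands,
                 channel_names = psd$channel_names),
            class = "band_peak_features")
}

#' Flatten features into a single numeric vector
#'
#' @param x a feature object.
#' @param ... method-specific options.
#' @return numeric vector.
#' @export
feature_vector <- function(x, ...) UseMethod("feature_vector")

#' @describeIn feature_vector window-major flattening of the n x 5 timbre
#'   matrix (each window's five descriptors contiguous); length `5 * n`.
#' @export
feature_vector.timbre_features <- function(x, ...) {
  as.vector(t(x$values))
}

#' @describeIn feature_vector channel-major flattening,
#'   `(peak_freq, peak_power)` per band per channel; length
#'   `2 * n_bands * n_channels` (320 for the DEAP layout). Peak powers are
#'   log10-transformed by default since line powers span decades.
#' @param log_power take `log10(peak_power + 1e-15)` (band_peak method).
#' @export
feature_vector.band_peak_features <- function(x, log_power = TRUE, ...) {
  v <- x$values
  if (log_power) v[, , 2L] <- log10(v[, , 2L] + 1e-15)
  as.vector(aperm(v, c(3L, 2L, 1L)))
}

#' @export
as.data.frame.band_peak_features <- function(x, ...) {
  g <- expand.grid(channel = x$channel_names, band = x$bands$name,
                   stringsAsFactors = FALSE)
  data.frame(g,
             peak_freq = as.vector(x$values[, , 1L]),
             peak_power = as.vector(x$values[, , 2L]),
             row.names = NULL)
}

#' Write band-peak features as CSV
#'
#' Header: `subject_id,trial_id,channel,band,peak_freq,peak_power`.
#'
#' @param x a `band_peak_features` object.
#' @param path output file.
#' @param subject_id,trial_id identifiers written into every row.
#' @return `path`, invisibly.
#' @export
write_band_peak_csv <- function(x, path, subject_id = "subject",
                                trial_id = "trial") {
  stopifnot(inherits(x, "band_peak_features"))
  df <- data.frame(subject_id = subject_id, trial_id = trial_id,
                   as.data.frame(x))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation between channels across trials
#'
#' Summarizes each channel of each trial by a scalar (default: total
#' band-limited power, the PSD integral over `band`) and correlates the
#' per-trial summaries between channels. Used to compare electrodes such as
#' the prefrontal (Fp1, Fp2) and parietal (P3, P4) pairs.
#'
#' @param trials list of [eeg_trial()] objects (same channel sets).
#' @param channels channel names to include (default: all).
#' @param band numeric `c(lo, hi)` in Hz for the power summary.
#' @param summary_fn optional custom summary `function(samples, sample_rate)`
#'   replacing the band-power summary.
#' @return symmetric correlation matrix with unit diagonal. Channels with
#'   zero variance across trials get `NA` entries and are listed in the
#'   `"flagged"` attribute instead of propagating NaN.
#' @export
channel_correlation <- function(trials, channels = NULL,
                                band = c(0.5, 45), summary_fn = NULL) {
  stopifnot(length(trials) >= 2L)
  ch_all <- trials[[1L]]$channel_names
  channels <- channels %||% ch_all
  if (length(channels) < 2L) {
    abort_museeg("need at least two channels", "museeg_error_bad_channels")
  }
  missing_ch <- setdiff(channels, ch_all)
  if (length(missing_ch)) {
    abort_museeg(paste("unknown channels:", paste(missing_ch, collapse = ", ")),
                 "museeg_error_bad_channels")
  }
  summaries <- vapply(trials, function(tr) {
    if (!is.null(summary_fn)) {
      vapply(channels, function(ch)
        summary_fn(tr$data[ch, ], tr$sample_rate), numeric(1))
    } else {
      psd <- compute_psd(tr)
      df <- psd$freqs[2L] - psd$freqs[1L]
      idx <- psd$freqs >= band[1L] & psd$freqs <= band[2L]
      rowSums(psd$power[match(channels, psd$channel_names), idx,
                        drop = FALSE]) * df
    }
  }, numeric(length(channels)))
  summaries <- t(summaries)  # trials x channels
  sds <- apply(summaries, 2L, sd)
  flagged <- channels[sds == 0]
  r <- suppressWarnings(cor(summaries))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  dimnames(r) <- list(channels, channels)
  attr(r, "flagged") <- flagged
  r
}
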