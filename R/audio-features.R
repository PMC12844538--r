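# Timbre descriptors from short-time magnitude spectra.
#
# Audio is cut into 1-second windows with 50% overlap (118 windows for a
# 60-second track under the strict end rule), each window is Hann-tapered and
# transformed, and five spectral-shape descriptors are computed per window:
# centroid, spread, skewness, entropy and flux. All descriptors are moments
# (or the Shannon entropy) of the L1-normalized magnitude distribution, so
# they are invariant to overall gain.

timbre_feature_names <- c("centroid", "spread", "skewness", "entropy", "flux")

#' Cut a track into overlapping analysis windows
#'
#' Window `k` covers `[k * hop, k * hop + window_s)` seconds with
#' `hop = window_s * (1 - overlap)`. A window is emitted if and only if its
#' end lies strictly before the track duration, the rule that yields 118
#' windows for a 60 s track at 1 s / 50% overlap.
#'
#' @param track an [audio_track()].
#' @param window_s window length in seconds.
#' @param overlap fractional overlap between consecutive windows in `[0, 1)`.
#' @return An object of class `audio_windows`: a list with `frames` (list of
#'   sample vectors), `starts` (window start times, seconds), and the framing
#'   parameters. A window longer than the track gives zero frames, not an
#'   error.
#' @examples
#' tr <- audio_track(rnorm(4000), 2000)
#' length(extract_windows(tr)$frames)  # 2 s track -> 2 windows
#' @export
extract_windows <- function(track, window_s = 1.0, overlap = 0.5) {
  stopifnot(inherits(track, "audio_track"))
  if (!is_scalar_number(window_s) || window_s <= 0) {
    abort_museeg("window_s must be positive", "museeg_error_bad_window")
  }
  if (!is_scalar_number(overlap) || overlap < 0 || overlap >= 1) {
    abort_museeg("overlap must lie in [0, 1)", "museeg_error_bad_window")
  }
  sr <- track$sample_rate
  duration <- track_duration(track)
  hop_s <- window_s * (1 - overlap)
  win_n <- max(1L, as.integer(round(window_s * sr)))
  starts <- numeric(0)
  k <- 0
  while (k * hop_s + window_s < duration) {
    starts <- c(starts, k * hop_s)
    k <- k + 1
  }
  frames <- lapply(starts, function(s) {
    i0 <- as.integer(round(s * sr)) + 1L
    track$samples[i0:(i0 + win_n - 1L)]
  })
  structure(
    list(frames = frames, starts = starts, window_s = window_s,
         overlap = overlap, sample_rate = sr),
    class = "audio_windows"
  )
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)
}

#' Construct a spectral frame
#'
#' The magnitude spectrum over the non-negative frequency half, the common
#' substrate of all five timbre descriptors.
#'
#' @param magnitudes non-negative magnitudes per frequency bin.
#' @param bin_freqs strictly increasing non-negative bin frequencies (Hz),
#'   same length as `magnitudes`.
#' @param frame_start window start time in seconds (metadata only).
#' @return An object of class `spectral_frame`.
#' @export
spectral_frame <- function(magnitudes, bin_freqs, frame_start = 0) {
  if (length(magnitudes) != length(bin_freqs)) {
    abort_museeg("magnitudes and bin_freqs must have equal length",
                 "museeg_error_bad_spectrum")
  }
  if (any(!is.finite(magnitudes)) || any(magnitudes < 0)) {
    abort_museeg("magnitudes must be finite and non-negative",
                 "museeg_error_bad_spectrum")
  }
  if (bin_freqs[1L] < 0 || any(diff(bin_freqs) <= 0)) {
    abort_museeg("bin_freqs must be non-negative and strictly increasing",
                 "museeg_error_bad_spectrum")
  }
  structure(
    list(magnitudes = as.numeric(magnitudes),
         bin_freqs = as.numeric(bin_freqs),
         frame_start = frame_start),
    class = "spectral_frame"
  )
}

#' Magnitude spectrum of one analysis window
#'
#' Applies a Hann taper (reduces spectral leakage; switch off with
#' `taper = "none"`) and returns the magnitude of the discrete Fourier
#' transform over bins `0 .. floor(N/2)`, with `bin_freqs = k * sample_rate / N`.
#'
#' @param frame numeric sample vector (one window).
#' @param sample_rate sampling rate in Hz.
#' @param taper `"hann"` (default) or `"none"`.
#' @param frame_start start time carried into the result.
#' @return a [spectral_frame()]. An all-zero frame yields all-zero magnitudes.
#' @export
frame_spectrum <- function(frame, sample_rate, taper = c("hann", "none"),
                           frame_start = 0) {
  taper <- match.arg(taper)
  n <- length(frame)
  if (n < 1L) abort_museeg("frame must be non-empty", "museeg_error_empty_frame")
  w <- if (taper == "hann") hann_window(n) else rep(1, n)
  X <- fft(frame * w)
  k <- 0:(n %/% 2L)
  spectral_frame(Mod(X[k + 1L]), k * sample_rate / n, frame_start)
}

# Vectorized descriptor core: mags is a K x n matrix of magnitude spectra
# (columns are windows), freqs the shared bin grid. Returns an n x 4 matrix
# (centroid, spread, skewness, entropy); flux needs window pairs and is
# computed separately. Zero-mass columns follow the silence conventions:
# every descriptor is 0.
spectral_moments_matrix <- function(mags, freqs) {
  K <- nrow(mags)
  tot <- colSums(mags)
  nz <- tot > 0
  p <- sweep(mags, 2L, ifelse(nz, tot, 1), "/")
  p[, !nz] <- 0
  centroid <- colSums(freqs * p)
  Fc <- matrix(freqs, K, ncol(mags)) - rep(centroid, each = K)
  m2 <- pmax(colSums(Fc^2 * p), 0)
  spread <- sqrt(m2)
  m3 <- colSums(Fc^3 * p)
  skewness <- ifelse(spread > 0, m3 / spread^3, 0)
  plogp <- p * log(p)
  plogp[p == 0] <- 0
  entropy <- if (K > 1L) -colSums(plogp) / log(K) else rep(0, ncol(mags))
  entropy[!nz] <- 0
  cbind(centroid = centroid, spread = spread,
        skewness = skewness, entropy = entropy)
}

#' Spectral centroid of a frame
#'
#' Center of mass of the magnitude spectrum,
#' \eqn{C = \sum_k f_k p_k} with \eqn{p_k} the L1-normalized magnitudes.
#' Returns 0 for an all-zero spectrum.
#'
#' @param s a [spectral_frame()].
#' @return centroid in Hz.
#' @export
spectral_centroid <- function(s) {
  stopifnot(inherits(s, "spectral_frame"))
  unname(spectral_moments_matrix(cbind(s$magnitudes), s$bin_freqs)[1L, "centroid"])
}

#' Spectral spread of a frame
#'
#' Width of the magnitude distribution around the centroid,
#' \eqn{\sqrt{\sum_k (f_k - C)^2 p_k}}; 0 for a zero or single-line spectrum.
#'
#' @inheritParams spectral_centroid
#' @return spread in Hz (non-negative).
#' @export
spectral_spread <- function(s) {
  stopifnot(inherits(s, "spectral_frame"))
  unname(spectral_moments_matrix(cbind(s$magnitudes), s$bin_freqs)[1L, "spread"])
}

#' Spectral skewness of a frame
#'
#' Standardized third moment \eqn{\sum_k (f_k - C)^3 p_k / \sigma^3},
#' measuring asymmetry of the spectral shape; 0 by convention when the
#' spread is 0.
#'
#' @inheritParams spectral_centroid
#' @return dimensionless skewness.
#' @export
spectral_skewness <- function(s) {
  stopifnot(inherits(s, "spectral_frame"))
  unname(spectral_moments_matrix(cbind(s$magnitudes), s$bin_freqs)[1L, "skewness"])
}

#' Normalized spectral entropy of a frame
#'
#' Shannon entropy of the L1-normalized magnitudes divided by `log(K)` over
#' the `K` bins, so the value lies in `[0, 1]`: 0 for a pure line, 1 for a
#' flat spectrum. The log base cancels in the normalization.
#'
#' @inheritParams spectral_centroid
#' @return entropy in `[0, 1]`.
#' @export
spectral_entropy <- function(s) {
  stopifnot(inherits(s, "spectral_frame"))
  unname(spectral_moments_matrix(cbind(s$magnitudes), s$bin_freqs)[1L, "entropy"])
}

#' Spectral flux between consecutive frames
#'
#' Euclidean norm of the difference between the L1-normalized magnitude
#' vectors of the current and previous windows; 0 for the first window
#' (`previous = NULL`).
#'
#' @param current a [spectral_frame()].
#' @param previous the preceding [spectral_frame()], or `NULL`.
#' @return non-negative flux.
#' @export
spectral_flux <- function(current, previous = NULL) {
  stopifnot(inherits(current, "spectral_frame"))
  if (is.null(previous)) return(0)
  stopifnot(inherits(previous, "spectral_frame"))
  if (length(current$magnitudes) != length(previous$magnitudes)) {
    abort_museeg("flux requires frames with equal bin counts",
                 "museeg_error_bin_mismatch")
  }
  l1norm <- function(m) {
    tot <- sum(m)
    if (tot > 0) m / tot else m * 0
  }
  sqrt(sum((l1norm(current$magnitudes) - l1norm(previous$magnitudes))^2))
}

#' Per-window timbre feature matrix for a track
#'
#' Windows the track ([extract_windows()]), computes each window's magnitude
#' spectrum and assembles the five timbre descriptors in the fixed column
#' order (centroid, spread, skewness, entropy, flux), rows ordered by window
#' start. The flux of the first window is 0.
#'
#' @inheritParams extract_windows
#' @param taper passed to [frame_spectrum()].
#' @return An object of class `timbre_features`: list with `values`
#'   (n_windows x 5 matrix), `window_starts` (seconds) and `track_id`.
#' @examples
#' tr <- audio_track(sin(2 * pi * 440 * (0:15999) / 4000), 4000, "tone")
#' tf <- track_features(tr)
#' dim(tf$values)  # 7 windows x 5 descriptors for a 4 s track
#' @export
track_features <- function(track, window_s = 1.0, overlap = 0.5,
                           taper = c("hann", "none")) {
  taper <- match.arg(taper)
  win <- extract_windows(track, window_s = window_s, overlap = overlap)
  nw <- length(win$frames)
  if (nw == 0L) {
    abort_museeg(
      sprintf("track too short for feature extraction: duration must exceed the window length of %g s", window_s),
      "museeg_error_track_too_short", minimum_duration = window_s)
  }
  n <- length(win$frames[[1L]])
  W <- matrix(unlist(win$frames, use.names = FALSE), nrow = n)
  w <- if (taper == "hann") hann_window(n) else rep(1, n)
  X <- stats::mvfft(W * w)
  k <- 0:(n %/% 2L)
  mags <- Mod(X[k + 1L, , drop = FALSE])
  freqs <- k * win$sample_rate / n
  vals <- spectral_moments_matrix(mags, freqs)
  tot <- colSums(mags)
  q <- sweep(mags, 2L, ifelse(tot > 0, tot, 1), "/")
  q[, tot == 0] <- 0
  flux <- c(0, if (nw > 1L) sqrt(colSums((q[, -1L, drop = FALSE] -
                                          q[, -nw, drop = FALSE])^2)))
  values <- cbind(vals, flux = flux)
  colnames(values) <- timbre_feature_names
  structure(
    list(values = values, window_starts = win$starts,
         track_id = track$track_id),
    class = "timbre_features"
  )
}

#' @export
print.timbre_features <- function(x, ...) {
  cat(sprintf("<timbre_features '%s': %d windows x 5 descriptors>\n",
              x$track_id, nrow(x$values)))
  invisible(x)
}

#' @export
as.data.frame.timbre_features <- function(x, ...) {
  data.frame(track_id = x$track_id, window_start = x$window_starts,
             x$values, row.names = NULL)
}

#' Write a timbre feature matrix as CSV
#'
#' Header: `track_id,window_start,centroid,spread,skewness,entropy,flux`.
#'
#' @param x a `timbre_features` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timbre_csv <- function(x, path) {
  stopifnot(inherits(x, "timbre_features"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
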