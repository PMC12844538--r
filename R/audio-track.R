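# Audio container and resampling.

#' Construct an audio track
#'
#' A mono waveform with its sample rate, the raw-audio atom used both by the
#' timbre-feature extractor and by the waveform branch of the fusion model.
#'
#' @param samples numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz (positive integer-valued scalar).
#' @param track_id identifier carried through feature tables.
#' @return An object of class `audio_track` with fields `samples`,
#'   `sample_rate` and `track_id`.
#' @examples
#' tr <- audio_track(sin(2 * pi * 440 * (0:999) / 8000), 8000, "a440")
#' track_duration(tr)
#' @export
audio_track <- function(samples, sample_rate, track_id = "track") {
  if (length(samples) < 1L) {
    abort_museeg("audio track must contain at least one sample",
                 "museeg_error_empty_track")
  }
  if (!is_scalar_number(sample_rate) || sample_rate <= 0) {
    abort_museeg("sample_rate must be a positive number (Hz)",
                 "museeg_error_bad_rate")
  }
  if (!all(is.finite(samples))) {
    abort_museeg("audio samples must be finite", "museeg_error_nonfinite")
  }
  structure(
    list(samples = as.numeric(samples),
         sample_rate = as.numeric(sample_rate),
         track_id = as.character(track_id)),
    class = "audio_track"
  )
}

#' Duration of an audio track in seconds
#' @param track an [audio_track()].
#' @return duration in seconds.
#' @export
track_duration <- function(track) {
  stopifnot(inherits(track, "audio_track"))
  length(track$samples) / track$sample_rate
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track '%s': %.2f s @ %g Hz>\n",
              x$track_id, track_duration(x), x$sample_rate))
  invisible(x)
}

#' Resample an audio track
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) and inverse-transformed at the new length. Exact
#' for band-limited content and free of the numerical instability that very
#' narrow IIR anti-alias filters exhibit at large decimation ratios.
#'
#' @param track an [audio_track()].
#' @param rate target sample rate in Hz.
#' @return an [audio_track()] at the requested rate.
#' @export
resample_track <- function(track, rate) {
  stopifnot(inherits(track, "audio_track"))
  if (!is_scalar_number(rate) || rate <= 0) {
    abort_museeg("target rate must be positive", "museeg_error_bad_rate")
  }
  if (isTRUE(all.equal(rate, track$sample_rate))) return(track)
  x <- track$samples
  n <- length(x)
  m <- max(1L, as.integer(round(n * rate / track$sample_rate)))
  X <- fft(x)
  Y <- complex(m)
  half <- min(n, m) %/% 2L
  Y[1L] <- X[1L]
  if (half >= 1L) {
    Y[seq_len(half) + 1L] <- X[seq_len(half) + 1L]
    neg <- seq_len(max(half - 1L, 0L))
    if (length(neg)) Y[m - neg + 1L] <- X[n - neg + 1L]
    if (m %% 2L == 0L && half == m %/% 2L) {
      # shared Nyquist bin must be real for a real output signal
      Y[half + 1L] <- complex(real = Re(Y[half + 1L]))
    }
  }
  y <- Re(fft(Y, inverse = TRUE)) / n
  audio_track(y, rate, track$track_id)
}
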