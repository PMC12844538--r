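# Shared fixtures: tiny configurations and independent oracles used across
# test files. Everything is generated in code; no binary fixtures.

# A fusion config small enough that forward/backward passes are instant.
tiny_fusion_config <- function(dropout = 0.25, ...) {
  fusion_config(mlp_hidden = c(16L, 16L), conv_filters = 4L,
                conv_kernel = 3L, dw_filters = 8L, dw_kernel = 5L,
                pool_factor = 2L, dropout = dropout, dw2_kernel = 3L,
                pointwise_filters = 8L, fc_intermediate = 6L, ...)
}

# A synthetic config small enough that full feature preparation is fast:
# 4 s trials keep audio synthesis, PSD and timbre extraction cheap while
# preserving every pipeline stage.
tiny_synth_config <- function(n_subjects = 2L, n_trials = 4L, seed = 11L,
                              ...) {
  synthetic_config(n_subjects = n_subjects, n_trials = n_trials,
                   trial_seconds = 4, audio_rate = 4000, seed = seed, ...)
}

# Construct a psd_spectrum directly (bypasses compute_psd) so band-peak
# extraction can be tested against arbitrary spectra.
make_psd <- function(power, freqs, channel_names = NULL) {
  channel_names <- channel_names %||% sprintf("ch%02d", seq_len(nrow(power)))
  structure(list(freqs = freqs, power = power,
                 channel_names = channel_names, sample_rate = 2 * max(freqs),
                 method = "synthetic"),
            class = "psd_spectrum")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate under a seed without disturbing the suite's RNG stream.
with_seed_test <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Independent brute-force oracle for the five timbre descriptors, written
# as plain sums over bins (no shared code with the package internals).
oracle_descriptors <- function(m, f) {
  tot <- sum(m)
  if (tot == 0) return(c(centroid = 0, spread = 0, skewness = 0, entropy = 0))
  p <- m / tot
  C <- 0
  for (k in seq_along(f)) C <- C + f[k] * p[k]
  v <- 0
  for (k in seq_along(f)) v <- v + (f[k] - C)^2 * p[k]
  spread <- sqrt(v)
  skew <- 0
  if (spread > 0) {
    s3 <- 0
    for (k in seq_along(f)) s3 <- s3 + (f[k] - C)^3 * p[k]
    skew <- s3 / spread^3
  }
  H <- 0
  for (k in seq_along(f)) if (p[k] > 0) H <- H - p[k] * log(p[k])
  c(centroid = C, spread = spread, skewness = skew,
    entropy = H / log(length(f)))
}

oracle_flux <- function(m_cur, m_prev) {
  norm1 <- function(m) if (sum(m) > 0) m / sum(m) else m * 0
  sqrt(sum((norm1(m_cur) - norm1(m_prev))^2))
}
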