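# Windowing and the five timbre descriptors.

test_that("windowing follows the strict end rule", {
  tr60 <- audio_track(numeric(60 * 8000), 8000)
  expect_length(extract_windows(tr60)$frames, 118L)

  short <- audio_track(numeric(4000), 8000)  # 0.5 s: window cannot fit
  expect_length(extract_windows(short, window_s = 1)$frames, 0L)

  two <- extract_windows(audio_track(numeric(4000), 2000))  # 2.0 s
  expect_length(two$frames, 2L)
  expect_equal(two$starts, c(0, 0.5))
})

test_that("window counts match brute-force enumeration", {
  set.seed(101)
  sr <- 200
  for (i in 1:200) {
    dur <- runif(1, 0.3, 6)
    win <- runif(1, 0.1, 2)
    ov <- runif(1, 0, 0.9)
    tr <- audio_track(numeric(max(1L, round(dur * sr))), sr)
    got <- length(extract_windows(tr, win, ov)$frames)
    hop <- win * (1 - ov)
    expected <- 0L
    k <- 0
    while (k * hop + win < track_duration(tr)) {
      expected <- expected + 1L
      k <- k + 1
    }
    expect_identical(got, expected)
  }
})

test_that("window parameters and empty tracks are validated", {
  expect_error(audio_track(numeric(0), 8000),
               class = "museeg_error_empty_track")
  tr <- audio_track(numeric(100), 100)
  expect_error(extract_windows(tr, window_s = -1),
               class = "museeg_error_bad_window")
  expect_error(extract_windows(tr, overlap = 1),
               class = "museeg_error_bad_window")
})

test_that("frame_spectrum locates pure and mixed tones", {
  n <- 8192
  sr <- 8192
  t <- (0:(n - 1)) / sr
  sf <- frame_spectrum(sin(2 * pi * 1000 * t), sr)
  expect_equal(sf$bin_freqs[which.max(sf$magnitudes)], 1000)

  zero <- frame_spectrum(numeric(256), sr)
  expect_true(all(zero$magnitudes == 0))

  two <- frame_spectrum(sin(2 * pi * 500 * t) + sin(2 * pi * 2000 * t), sr)
  top2 <- two$bin_freqs[order(two$magnitudes, decreasing = TRUE)[1:2]]
  expect_setequal(top2, c(500, 2000))
})

test_that("descriptors reproduce hand-computed values", {
  # point mass
  one <- spectral_frame(c(0, 5, 0), c(500, 1000, 1500))
  expect_equal(spectral_centroid(one), 1000)
  expect_equal(spectral_spread(one), 0)
  expect_equal(spectral_skewness(one), 0)
  expect_equal(spectral_entropy(one), 0)

  # two equal lines: symmetric
  sym <- spectral_frame(c(1, 1), c(100, 300))
  expect_equal(spectral_centroid(sym), 200)
  expect_equal(spectral_spread(sym), 100)
  expect_equal(spectral_skewness(sym), 0)

  # weighted two-line spectrum: second and third standardized moments
  wt <- spectral_frame(c(0.75, 0.25), c(100, 300))
  expect_equal(spectral_spread(wt), sqrt(7500))
  expect_equal(spectral_skewness(wt), 750000 / sqrt(7500)^3)

  # entropy closed forms
  K8 <- spectral_frame(rep(1, 8), 1:8)
  expect_equal(spectral_entropy(K8), 1)
  two8 <- spectral_frame(c(1, 1, rep(0, 6)), 1:8)
  expect_equal(spectral_entropy(two8), log(2) / log(8))

  # zero spectrum conventions
  z <- spectral_frame(c(0, 0), c(1, 2))
  expect_equal(spectral_centroid(z), 0)
  expect_equal(spectral_entropy(z), 0)

  # flux
  a <- spectral_frame(c(1, 0), c(1, 2))
  b <- spectral_frame(c(0, 1), c(1, 2))
  expect_equal(spectral_flux(b, a), sqrt(2))
  expect_equal(spectral_flux(a, NULL), 0)
  expect_equal(spectral_flux(a, a), 0)
  expect_error(spectral_flux(a, spectral_frame(1, 1)),
               class = "museeg_error_bin_mismatch")
})

test_that("descriptors match a brute-force oracle on random spectra", {
  set.seed(202)
  for (i in 1:200) {
    m <- runif(16, 0, 10) * rbinom(16, 1, 0.8)
    f <- sort(runif(16, 0, 4000))
    sf <- spectral_frame(m, f)
    ref <- oracle_descriptors(m, f)
    expect_equal(spectral_centroid(sf), ref[["centroid"]], tolerance = 1e-9)
    expect_equal(spectral_spread(sf), ref[["spread"]], tolerance = 1e-9)
    expect_equal(spectral_skewness(sf), ref[["skewness"]], tolerance = 1e-9)
    expect_equal(spectral_entropy(sf), ref[["entropy"]], tolerance = 1e-9)
  }
})

test_that("descriptors are invariant to magnitude scaling", {
  set.seed(303)
  f <- sort(runif(32, 0, 4000))
  for (i in 1:20) {
    m <- runif(32)
    c_ <- runif(1, 1e-4, 1e4)
    s1 <- spectral_frame(m, f)
    s2 <- spectral_frame(m * c_, f)
    expect_equal(spectral_centroid(s1), spectral_centroid(s2),
                 tolerance = 1e-10)
    expect_equal(spectral_spread(s1), spectral_spread(s2),
                 tolerance = 1e-10)
    expect_equal(spectral_skewness(s1), spectral_skewness(s2),
                 tolerance = 1e-10)
    expect_equal(spectral_entropy(s1), spectral_entropy(s2),
                 tolerance = 1e-10)
    expect_equal(spectral_flux(s2, s1), 0, tolerance = 1e-10)
  }
})

test_that("track_features returns an ordered, well-formed matrix", {
  sr <- 1000
  t <- (0:(10 * sr - 1)) / sr
  tone <- audio_track(sin(2 * pi * 100 * t), sr, "tone100")
  tf <- track_features(tone)
  expect_identical(dim(tf$values), c(18L, 5L))
  expect_identical(colnames(tf$values),
                   c("centroid", "spread", "skewness", "entropy", "flux"))
  expect_identical(tf$window_starts, seq(0, 8.5, by = 0.5))

  # matrix invariants
  expect_true(all(tf$values[, "spread"] >= 0))
  expect_true(all(tf$values[, "entropy"] >= 0 & tf$values[, "entropy"] <= 1))
  expect_true(all(tf$values[, "flux"] >= 0))
  expect_identical(tf$values[1L, "flux"], c(flux = 0))

  # 100 cycles per hop: every window sees identical content, so the
  # spectrum is constant and flux vanishes after the first row
  expect_lt(max(tf$values[-1L, "flux"]), 1e-10)

  # stationary tone: centroid stays at the tone frequency
  expect_true(all(abs(tf$values[, "centroid"] - 100) < 3))
})

test_that("a 60 s track yields the 118 x 5 feature matrix", {
  tr <- audio_track(rnorm(60 * 4000), 4000)
  tf <- track_features(tr)
  expect_identical(dim(tf$values), c(118L, 5L))
})

test_that("too-short tracks raise a structured error naming the minimum", {
  tr <- audio_track(numeric(500), 1000)
  err <- expect_error(track_features(tr),
                      class = "museeg_error_track_too_short")
  expect_match(conditionMessage(err), "1")
  expect_equal(err$minimum_duration, 1)
})

test_that("timbre CSV export has the documented header", {
  tr <- audio_track(rnorm(3000), 1000, "t1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_timbre_csv(track_features(tr), path)
  df <- read.csv(path)
  expect_identical(names(df), c("track_id", "window_start", "centroid",
                                "spread", "skewness", "entropy", "flux"))
  expect_identical(nrow(df), 4L)  # 3 s track -> starts 0, 0.5, 1, 1.5
})
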