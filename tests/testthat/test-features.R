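test_that("time-domain statistics match their closed forms", {
  # constant positive window
  tf <- time_features(rep(3, 20))
  expect_equal(unname(tf["crest"]), 1)
  expect_equal(unname(tf["ptp"]), 0)
  expect_equal(unname(tf["mse"]), 9)
  expect_equal(unname(tf["min_sq"]), 9)
  expect_equal(unname(tf["skewness"]), 0)    # sigma = 0 convention
  expect_equal(unname(tf["entropy"]), 0)
  expect_equal(unname(tf["kurtosis"]), 81)   # non-central mean of x^4

  # full sine period: crest factor sqrt(2)
  x <- sin(2 * pi * (0:59) / 60)
  expect_equal(unname(time_features(x)["crest"]), sqrt(2), tolerance = 1e-6)

  # 90th percentile of 1..10 is the order statistic at position 9.1
  expect_equal(unname(time_features(1:10)["p90"]), 9.1)
  # brute-force the interpolated order statistic on random draws
  set.seed(4)
  for (i in 1:10) {
    x <- stats::rnorm(sample(5:40, 1))
    xs <- sort(x); pos <- 1 + 0.9 * (length(x) - 1)
    expected <- xs[floor(pos)] +
      (pos - floor(pos)) * (xs[ceiling(pos)] - xs[floor(pos)])
    expect_equal(unname(time_features(x)["p90"]), expected)
  }

  # all-zero window: crest and clearance fall back to 0
  tf0 <- time_features(rep(0, 10))
  expect_equal(unname(tf0[c("crest", "clearance")]), c(0, 0))
  # literal clearance option reproduces the crest factor
  x <- stats::rnorm(30)
  expect_equal(unname(time_features(x, clearance_literal = TRUE)["clearance"]),
               unname(time_features(x)["crest"]))
})

test_that("periodogram is Parseval-consistent and matches a naive DFT", {
  fs <- 30; n <- 60
  t <- (0:(n - 1)) / fs
  # single 5 Hz tone peaks at the 5 Hz bin
  x <- sin(2 * pi * 5 * t)
  sp <- spectrum_window(x, fs)
  expect_equal(sp$frequencies[which.max(sp$amplitude)], 5)
  # zero vector: all power zero
  expect_equal(max(spectrum_window(rep(0, n), fs)$power), 0)

  set.seed(9)
  for (i in 1:8) {
    x <- sin(2 * pi * 1 * t) + 0.7 * sin(2 * pi * 5 * t + 1) +
      stats::rnorm(n, sd = 0.3)
    sp <- spectrum_window(x, fs)
    ref <- naive_dft_power(x, fs)
    expect_equal(sp$power, ref$power, tolerance = 1e-9)
    expect_equal(sp$amplitude, ref$amplitude, tolerance = 1e-9)
    # sum(power) * df equals the population variance
    expect_equal(sum(sp$power) * fs / n, mean((x - mean(x))^2),
                 tolerance = 1e-9)
    # band areas agree with the independent trapezoid oracle
    for (band in list(c(0.5, 3), c(3, 8), c(1, 1.5), c(3.5, 15))) {
      expect_equal(band_area(sp, band[1], band[2]),
                   naive_band_area(ref$frequencies, ref$power,
                                   band[1], band[2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("band areas are nonnegative, additive, and clip at Nyquist", {
  set.seed(2)
  x <- stats::rnorm(60)
  sp <- spectrum_window(x, 30)
  expect_true(band_area(sp, 0.5, 3) >= 0)
  for (abc in list(c(0.5, 3, 8), c(1, 1.5, 4.2), c(0, 7.3, 15))) {
    expect_equal(band_area(sp, abc[1], abc[2]) + band_area(sp, abc[2], abc[3]),
                 band_area(sp, abc[1], abc[3]), tolerance = 1e-9)
  }
  expect_warning(a <- band_area(sp, 3.5, 20), "Nyquist")
  expect_equal(a, band_area(sp, 3.5, 15))
})

test_that("spectral features read single tones and mixtures correctly", {
  fs <- 30; n <- 60; t <- (0:(n - 1)) / fs
  sp5 <- spectrum_window(sin(2 * pi * 5 * t), fs)
  sf5 <- spectral_features(sp5)
  expect_equal(unname(sf5["avg_freq"]), 5, tolerance = fs / n)
  # flat zero spectrum: everything 0
  sf0 <- spectral_features(spectrum_window(rep(0, n), fs))
  expect_equal(unname(sf0), c(0, 0, 0))
  # equal-amplitude two-tone mixture: two comparable power peaks, comparable
  # band areas either side of 3 Hz
  spm <- spectrum_window(sin(2 * pi * 1 * t) + sin(2 * pi * 5 * t), fs)
  sfm <- spectral_features(spm)
  p1 <- max(spm$power)
  expect_gt(unname(sfm["second_power_peak"]) / p1, 0.95)
  expect_equal(band_area(spm, 0.5, 3), band_area(spm, 3, 8), tolerance = 0.05)
})

test_that("freezing index separates freeze-band from locomotor-band tones", {
  fs <- 30; n <- 60; t <- (0:(n - 1)) / fs
  expect_gte(freezing_index(sin(2 * pi * 5 * t), fs), 100)
  expect_lte(freezing_index(sin(2 * pi * 1 * t), fs), 0.01)
  expect_equal(freezing_index(rep(0, n), fs), 1e6)   # capped degenerate case
})

test_that("feature matrix assembly is deterministic and validates its spec", {
  rec <- simulate_recording(tiny_sim_params(), 1, with_fog = TRUE)
  sig <- derive_signals(normalize_sequence(
    interpolate_low_confidence(rec$sequence)))
  win <- label_windows(slide_windows(sig), rec$annotations, 30,
                       n_frames(rec$sequence))
  spec3 <- fog_feature_spec(channels = "speed_RHeel_y",
                            statistics = c("mean_abs", "fi", "band_0p5_3"))
  one <- list(list(signals = sig, windows = win[1, , drop = FALSE]))
  fm1 <- build_feature_matrix(one, spec3)
  expect_equal(nrow(fm1), 1)
  expect_equal(length(feature_cols(fm1)), 3)
  expect_true(all(feature_cols(fm1) %in% names(fm1)))

  # permuting window order permutes rows only
  perm <- sample(nrow(win))
  fm_a <- build_feature_matrix(list(list(signals = sig, windows = win)), spec3)
  fm_b <- build_feature_matrix(list(list(signals = sig, windows = win[perm, ])),
                               spec3)
  fm_b <- fm_b[order(fm_b$t_start), ]; rownames(fm_b) <- NULL
  expect_equal(fm_a, fm_b, ignore_attr = TRUE)

  # vectorized extraction agrees with the scalar per-window functions
  i <- which(win$fog_label == "fog")[1]
  x <- sig$data[win$i_start[i]:(win$i_start[i] + win$n[i] - 1), "speed_RHeel_y"]
  expect_equal(fm_a$mean_abs__speed_RHeel_y[i],
               unname(time_features(x)["mean_abs"]))
  expect_equal(fm_a$fi__speed_RHeel_y[i], freezing_index(x, 30),
               tolerance = 1e-9)
  expect_equal(fm_a$band_0p5_3__speed_RHeel_y[i],
               band_area(spectrum_window(x, 30), 0.5, 3), tolerance = 1e-9)

  expect_error(fog_feature_spec(statistics = "nope"), "unknown statistic")
  bad <- fog_feature_spec(channels = "no_such_channel")
  expect_error(build_feature_matrix(list(list(signals = sig, windows = win)),
                                    bad), "unknown channel")

  # YAML spec round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  write_feature_spec(spec3, f)
  expect_equal(read_feature_spec(f), spec3)
})
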