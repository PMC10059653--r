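test_that("calibration is the identity when off and the rational correction when on", {
  tr <- signal_trace(c(0, 100, 400), fs = 10, channel = "EDA")
  expect_identical(calibrate_trace(tr, calibration_params(mode = "off"))$samples, tr$samples)

  cal <- calibrate_trace(signal_trace(0, fs = 10, channel = "EDA"),
                         calibration_params(mode = "divide"))
  # direct substitution: f(0) = 0 - (2014 * 10000) / 512
  expect_equal(cal$samples, -39335.9375)

  expect_error(
    calibrate_trace(signal_trace(c(10, 512), fs = 10, channel = "EDA"),
                    calibration_params(mode = "divide")),
    class = "affectstream_singularity_error"
  )
})

test_that("wavelet transform reconstructs exactly at zero threshold and denoises a ramp", {
  set.seed(7)
  x <- cumsum(rnorm(500))
  y <- wavelet_denoise(x, levels = 3, threshold = 0)
  expect_lt(max(abs(x - y)) / max(abs(x)), 1e-8)

  const <- wavelet_denoise(rep(3.5, 256), levels = 3)
  expect_equal(const, rep(3.5, 256), tolerance = 1e-8)

  clean <- seq(0, 10, length.out = 1000)
  noisy <- clean + rnorm(1000, sd = 0.5)
  den <- wavelet_denoise(noisy, levels = 3)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den, clean), rmse(noisy, clean))

  expect_error(wavelet_denoise(1:4, levels = 3), class = "affectstream_invalid_argument")
})

test_that("Butterworth responses match the closed form and attenuate the stop band", {
  # H(D0) = 1/2 for any order
  for (n in 1:5) expect_equal(butterworth_gain(10, 10, n), 0.5)
  # monotone non-increasing over a frequency grid
  g <- butterworth_gain(seq(0, 50, by = 0.5), D0 = 10, n = 4)
  expect_true(all(diff(g) <= 0))

  fs <- 100
  dc <- signal_trace(rep(1, 1000), fs = fs, channel = "PPG")
  out <- lowpass_filter(dc, 10, 4)
  expect_true(all(abs(out$samples[200:800] - 1) < 0.01))

  t <- (0:999) / fs
  sine20 <- signal_trace(sin(2 * pi * 20 * t), fs = fs, channel = "PPG")
  amp <- max(abs(lowpass_filter(sine20, 10, 4)$samples[200:800]))
  expect_lte(amp, 0.1)

  expect_error(lowpass_filter(dc, 50, 4), class = "affectstream_invalid_argument")
})

test_that("digital filter gain is monotone non-increasing on sampled sines", {
  fs <- 100
  t <- (0:1999) / fs
  gains <- vapply(c(0.5, 2, 5, 8, 12, 16, 25, 40), function(f0) {
    y <- lowpass_filter(signal_trace(sin(2 * pi * f0 * t), fs = fs, channel = "PPG"), 10, 4)
    max(abs(y$samples[500:1500]))
  }, numeric(1))
  expect_true(all(diff(gains) <= 1e-6))
  expect_gt(gains[1], 0.99)
})

test_that("0-100 normalization scales by hand-checked min-max and is idempotent", {
  expect_equal(normalize_0_100(c(2, 7, 4)), c(0, 100, 40))
  y <- normalize_0_100(c(0, 25, 100))
  expect_identical(normalize_0_100(y), y)
  expect_equal(range(normalize_0_100(rnorm(100))), c(0, 100))
  expect_error(normalize_0_100(rep(2, 5)), class = "affectstream_degenerate_segment")
})

test_that("the preprocessing chain is deterministic", {
  s <- default_session()
  a <- preprocess_session(s)
  b <- preprocess_session(s)
  expect_identical(a$eda$samples, b$eda$samples)
  expect_identical(a$ppg$samples, b$ppg$samples)
})
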