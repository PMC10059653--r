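test_that("bpnn50 matches hand enumeration and honors the strict boundary", {
  # diffs {60, 10, 70} -> 2 of 3 exceed 50 ms
  expect_equal(bpnn50(c(800, 860, 870, 940)), 2 / 3)
  expect_equal(bpnn50(rep(800, 10)), 0)
  expect_equal(bpnn50(c(800, 850)), 0)  # exactly 50 ms excluded
  expect_error(bpnn50(800), class = "affectstream_invalid_argument")
})

test_that("bpnn50 equals a brute-force double-loop count on random interval lists", {
  brute <- function(iv, thr = 50) {
    n <- 0L
    for (i in seq_len(length(iv) - 1L)) {
      if (abs(iv[i + 1L] - iv[i]) > thr) n <- n + 1L
    }
    n / (length(iv) - 1L)
  }
  set.seed(123)
  for (rep in 1:250) {
    iv <- 800 + rnorm(sample(2:30, 1), sd = runif(1, 1, 120))
    expect_identical(bpnn50(iv), brute(iv))
  }
})

test_that("range and 1dmean match hand evaluation and their closed forms", {
  expect_equal(signal_range(c(2, 7, 4)), 5)
  expect_equal(signal_range(rep(1, 5)), 0)
  expect_equal(signal_range(-c(2, 7, 4)), 5)
  expect_error(signal_range(numeric(0)), class = "affectstream_invalid_argument")

  expect_equal(one_d_mean(c(1, 3, 6)), 2.5)
  expect_equal(one_d_mean(rep(4, 9)), 0)
  expect_error(one_d_mean(3), class = "affectstream_invalid_argument")
  # telescoping identity on random windows
  set.seed(11)
  for (rep in 1:100) {
    x <- rnorm(sample(2:200, 1))
    expect_equal(one_d_mean(x), (x[length(x)] - x[1]) / (length(x) - 1), tolerance = 1e-12)
  }
  # scale covariance of range
  x <- rnorm(50)
  expect_equal(signal_range(3.7 * x), 3.7 * signal_range(x))
})

test_that("beat detection recovers generator ground truth within one sample at 100 Hz", {
  p <- generate_ppg(quadrant_scenario("LANV", duration_s = 30, seed = 21), fs = 100)
  fid <- detect_beats(p$trace)
  expect_equal(nrow(fid), length(p$beat_times))
  expect_lte(max(abs(fid$t_main - p$beat_times)), 1 / 100 + 1e-9)

  # zero jitter: all recovered periods equal the base interval within a sample
  p0 <- generate_ppg(quadrant_scenario("HANV", duration_s = 30, seed = 4, ibi_jitter_ms = 0))
  iv <- beat_intervals_ms(detect_beats(p0$trace))
  expect_true(all(abs(iv - 800) <= 10 + 1e-9))

  expect_error(detect_beats(rep(0, 1000), fs = 100), class = "affectstream_insufficient_beats")
  expect_error(detect_beats(sin(2 * pi * (0:999) / 1000), fs = 100),
               class = "affectstream_insufficient_beats")
})

test_that("the feature catalogue has the stated family counts", {
  cat <- feature_catalog()
  counts <- table(cat$channel, cat$family)
  expect_equal(unname(counts["EDA", "time_domain"]), 24)
  expect_equal(unname(counts["PPG", "time_domain"]), 18)
  expect_equal(unname(counts["EDA", "physiological"]), 7)
  expect_equal(unname(counts["PPG", "physiological"]), 10)
  # one shared spectral mold for both channels
  expect_equal(unname(counts["EDA", "frequency_domain"]),
               unname(counts["PPG", "frequency_domain"]))
  expect_false(anyDuplicated(cat$name) > 0)
})

test_that("feature extraction is deterministic and flags absent pulse features", {
  ft <- default_features()
  expect_identical(ft, {
    ft2 <- extract_features(default_prepped())
    ft2
  })
  expect_setequal(setdiff(names(ft), c("window", "eda_n_min", "eda_n_max")),
                  feature_catalog()$name)

  # windowed pair where PPG is flat: pulse features absent, EDA present
  eda <- signal_trace(seq(0, 1, length.out = 1000) + rnorm(1000, sd = 0.01),
                      fs = 100, channel = "EDA")
  flat <- signal_trace(rep(1, 1000), fs = 100, channel = "PPG")
  row <- extract_features(eda, flat)
  expect_true(is.na(row$ppg_bpnn50[1]))
  expect_true(is.na(row$ppg_mean[1]))
  expect_false(is.na(row$eda_range[1]))
})
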