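test_that("scenario construction validates arguments and fills quadrant defaults", {
  sc <- quadrant_scenario("HANV", duration_s = 30, seed = 3)
  expect_identical(sc$eda_range_level, "high")
  expect_identical(sc$eda_trend, "rising")
  expect_identical(quadrant_scenario("LAPV")$eda_trend, "falling")
  expect_identical(quadrant_scenario("LANV")$pulse_range_level, "high")
  expect_identical(quadrant_scenario("HAPV")$pulse_slope_level, "high")
  expect_error(quadrant_scenario("HANV", duration_s = 5), class = "affectstream_invalid_argument")
  expect_error(quadrant_scenario("HANV", ibi_jitter_ms = -1), class = "affectstream_invalid_argument")
})

test_that("EDA extremum ordering follows the scenario trend in every window", {
  for (trend in c("rising", "falling")) {
    sc <- quadrant_scenario("HANV", duration_s = 40, seed = 11, eda_trend = trend)
    wins <- segment_windows(generate_eda(sc), 10)
    for (w in wins) {
      if (trend == "rising") expect_gt(w$n_max, w$n_min) else expect_lt(w$n_max, w$n_min)
    }
  }
})

test_that("generation is bit-identical under a fixed seed", {
  sc <- quadrant_scenario("LANV", seed = 42)
  expect_identical(generate_eda(sc)$samples, generate_eda(sc)$samples)
  p1 <- generate_ppg(sc)
  p2 <- generate_ppg(sc)
  expect_identical(p1$trace$samples, p2$trace$samples)
  expect_identical(p1$beat_times, p2$beat_times)
})

test_that("inter-beat jitter controls successive-difference exceedances", {
  no_jit <- generate_ppg(quadrant_scenario("HANV", seed = 5, ibi_jitter_ms = 0))
  expect_true(all(abs(diff(no_jit$ibis_ms)) < 1e-9))
  jit <- generate_ppg(quadrant_scenario("HANV", seed = 5, ibi_jitter_ms = 40,
                                        duration_s = 60))
  # fraction of successive-interval differences exceeding 50 ms, on the
  # generator's own ground-truth intervals
  frac <- mean(abs(diff(jit$ibis_ms)) > 50)
  expect_gt(frac, 0)
})

test_that("beat times are strictly increasing and beats carry all four landmarks", {
  p <- generate_ppg(quadrant_scenario("LANV", seed = 9))
  expect_true(all(diff(p$beat_times) > 0))
  fid <- detect_beats(p$trace)
  complete <- stats::complete.cases(fid[, c("t_main", "t_notch", "t_dicrotic", "t_anterior")])
  expect_gt(sum(complete), nrow(fid) - 2)
  # fiducial ordering invariant within each complete beat
  f <- fid[complete, ]
  expect_true(all(f$t_main < f$t_notch))
  expect_true(all(f$t_notch < f$t_dicrotic))
  expect_true(all(f$t_anterior > f$t_main & f$t_anterior < f$t_notch))
})

test_that("session assembly aligns labels to scenario boundaries", {
  s <- generate_session(list(
    quadrant_scenario("HANV", duration_s = 30, seed = 1),
    quadrant_scenario("LAPV", duration_s = 30, seed = 2)
  ))
  expect_identical(s$labels, c(rep("HANV", 3), rep("LAPV", 3)))
  single <- generate_session(list(quadrant_scenario("LANV", duration_s = 60, seed = 1)))
  expect_length(single$labels, 6)
  expect_error(generate_session(list()), class = "affectstream_invalid_argument")
  expect_error(
    generate_session(list(quadrant_scenario("HANV", duration_s = 15, seed = 1))),
    class = "affectstream_invalid_argument"
  )
})

test_that("high and low EDA range levels produce non-overlapping window ranges", {
  ranges <- function(level) {
    unlist(lapply(1:5, function(sd) {
      sc <- quadrant_scenario("HANV", seed = sd, eda_range_level = level)
      vapply(segment_windows(generate_eda(sc), 10), function(w) w$x_max - w$x_min, numeric(1))
    }))
  }
  expect_gt(min(ranges("high")), max(ranges("low")))
})
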