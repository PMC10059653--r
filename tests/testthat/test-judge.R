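test_that("the normalized threshold is the mean of min-max-normalized values", {
  st <- compute_threshold(c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(st$normalized, c(0, 0.25, 0.5, 0.75, 1.0))
  expect_equal(st$x_th, 0.5)

  expect_equal(compute_threshold(c(3, 9))$x_th, 0.5)  # {0, 1} symmetry

  # invariance under positive affine transforms of the raw stream
  x <- rnorm(20)
  expect_equal(compute_threshold(7.3 * x + 2)$x_th, compute_threshold(x)$x_th)

  expect_error(compute_threshold(rep(5, 10)), class = "affectstream_degenerate_threshold")

  # parameters frozen on the reference span; later values clipped to [0, 1]
  st2 <- compute_threshold(c(1, 2, 3, 10, -5), reference = 1:3)
  expect_equal(st2$x_min, 1)
  expect_equal(st2$x_max, 3)
  expect_equal(st2$normalized[4:5], c(1, 0))
})

test_that("hand-traced windows reproduce the rule tree's decisions", {
  th <- list(eda_range = 0.5, eda_1dmean = 0.5, ppg_bpnn50 = 0.5,
             ppg_range = 0.5, ppg_1dmean = 0.5)
  base <- list(eda_range = 0.2, eda_1dmean = 0.9, ppg_bpnn50 = 0.1,
               ppg_range = 0.9, ppg_1dmean = 0.9, n_max = 9, n_min = 0)

  # EDA guard fails, pulse guard fails -> UNDECIDED
  expect_identical(judge_window(base, th)$quadrant, "UNDECIDED")

  # falling EDA deflection with large range -> LAPV
  lapv <- modifyList(base, list(eda_range = 0.9, n_max = 0, n_min = 2))
  expect_identical(judge_window(lapv, th)$quadrant, "LAPV")

  # rising deflection with steep slope -> HANV
  hanv <- modifyList(base, list(eda_range = 0.9, n_max = 9, n_min = 0))
  expect_identical(judge_window(hanv, th)$quadrant, "HANV")

  # pulse branch: BpNN50 and range high -> LANV; range low but slope high -> HAPV
  lanv <- modifyList(base, list(ppg_bpnn50 = 0.7, ppg_range = 0.9))
  expect_identical(judge_window(lanv, th)$quadrant, "LANV")
  hapv <- modifyList(base, list(ppg_bpnn50 = 0.7, ppg_range = 0.2, ppg_1dmean = 0.7))
  expect_identical(judge_window(hapv, th)$quadrant, "HAPV")

  # boundary equality falls to the otherwise arm
  eq <- modifyList(base, list(eda_range = 0.5))
  expect_identical(judge_window(eq, th)$quadrant, "UNDECIDED")

  # conflicting branches resolve by fixed priority (HANV beats HAPV)
  both <- modifyList(hanv, list(ppg_bpnn50 = 0.7, ppg_range = 0.2, ppg_1dmean = 0.7))
  d <- judge_window(both, th)
  expect_identical(d$quadrant, "HANV")
  expect_true(any(grepl("priority", vapply(d$rule_trace, `[[`, "", "test"))))
})

test_that("the rule engine agrees with a literal nested-conditional transcription", {
  set.seed(99)
  for (i in 1:2000) {
    f <- random_feature_tuple()
    th <- random_thresholds()
    expect_identical(judge_window(f, th)$quadrant, oracle_judge(f, th))
  }
})

test_that("rule traces replay to the decision they record", {
  set.seed(17)
  for (i in 1:200) {
    f <- random_feature_tuple()
    th <- random_thresholds()
    d <- judge_window(f, th)
    expect_identical(judge_window(f, th)$quadrant, d$quadrant)
    if (d$quadrant != "UNDECIDED") expect_gt(length(d$rule_trace), 0)
  }
})

test_that("missing pulse features restrict judgment to the EDA branch", {
  th <- list(eda_range = 0.5, eda_1dmean = 0.5, ppg_bpnn50 = NA,
             ppg_range = NA, ppg_1dmean = NA)
  f <- list(eda_range = 0.9, eda_1dmean = 0.9, ppg_bpnn50 = NA,
            ppg_range = NA, ppg_1dmean = NA, n_max = 9, n_min = 0)
  d <- judge_window(f, th)
  expect_identical(d$quadrant, "HANV")
  expect_true(d$partial)
})

test_that("session judgment recovers generator labels and is deterministic", {
  s <- default_session()
  prep <- default_prepped()
  d1 <- judge_session(prep, features = default_features())
  d2 <- judge_session(prep, features = default_features())
  expect_identical(d1$quadrant, d2$quadrant)
  expect_true(all(d1$quadrant[d1$calibration] == "UNDECIDED"))
  expect_gte(judge_accuracy(d1, s$labels), 0.9)
  # exactly one decision per window
  expect_identical(d1$window, seq_len(nrow(d1)) - 1L)
})

test_that("decisions are invariant to positive affine rescaling of the raw channels", {
  s <- default_session(seed = 6)
  scaled <- s
  scaled$eda <- signal_trace(4.2 * s$eda$samples + 11, fs = s$fs, channel = "EDA")
  scaled$ppg <- signal_trace(0.37 * s$ppg$samples + 2, fs = s$fs, channel = "PPG")
  d0 <- judge_session(preprocess_session(s))
  d1 <- judge_session(preprocess_session(scaled))
  expect_identical(d0$quadrant, d1$quadrant)
})

test_that("degenerate sessions and short sessions raise typed errors", {
  flat <- list(
    eda = signal_trace(rep(1, 6000), fs = 100, channel = "EDA"),
    ppg = signal_trace(rep(2, 6000), fs = 100, channel = "PPG")
  )
  # constant signals cannot be normalized at all ...
  expect_error(preprocess_session(flat), class = "affectstream_degenerate_segment")
  # ... and give no usable feature stream if judged directly
  expect_error(suppressWarnings(judge_session(flat)),
               class = "affectstream_degenerate_threshold")
  s <- default_session()
  expect_error(judge_session(default_prepped(), calibration_windows = 12,
                             features = default_features()),
               class = "affectstream_invalid_argument")
})
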