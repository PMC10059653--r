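#' Quadrant scenario: the generator's description of one emotion segment
#'
#' A scenario fixes the statistical signature of one valence-arousal
#' quadrant in the two recorded channels. The canonical signatures are the
#' conditions the rule tree tests:
#'
#' * `HANV` -- high EDA range, rising deflection (max after min), high EDA slope;
#' * `LAPV` -- high EDA range, falling deflection (max before min);
#' * `LANV` -- high inter-beat-interval jitter and high pulse amplitude;
#' * `HAPV` -- high inter-beat-interval jitter, low pulse amplitude, rising
#'   pulse-amplitude envelope.
#'
#' All amplitudes are in arbitrary units: every downstream judgment is
#' min-max normalized, so only the relative structure matters.
#'
#' @param quadrant One of `"HAPV"`, `"HANV"`, `"LANV"`, `"LAPV"`.
#' @param duration_s Segment length in seconds (>= 10).
#' @param seed RNG seed; a fixed seed reproduces the segment bit for bit.
#' @param eda_range_level,pulse_range_level `"low"` or `"high"` window
#'   amplitude span. Defaults follow the quadrant signature.
#' @param eda_trend `"rising"` or `"falling"`: whether the window maximum
#'   comes after or before the minimum.
#' @param eda_slope_level `"low"` or `"high"`: magnitude of the EDA
#'   first-difference mean (high = monotone ramp across each window,
#'   low = tent shape with near-zero net slope).
#' @param ibi_jitter_ms Standard deviation (ms) of inter-beat-interval
#'   perturbations; drives BpNN50.
#' @param pulse_slope_level `"low"` or `"high"`: slope of the per-beat
#'   amplitude envelope within each window.
#' @param base_ibi_ms Mean inter-beat interval in ms (> 0).
#' @return A `quadrant_scenario` object.
#' @export
quadrant_scenario <- function(quadrant = c("HANV", "LANV", "LAPV", "HAPV"),
                              duration_s = 30,
                              seed = 1L,
                              eda_range_level = NULL,
                              eda_trend = NULL,
                              eda_slope_level = NULL,
                              ibi_jitter_ms = NULL,
                              pulse_range_level = NULL,
                              pulse_slope_level = NULL,
                              base_ibi_ms = 800) {
  quadrant <- match.arg(quadrant)
  defaults <- list(
    HANV = list(eda_range_level = "high", eda_trend = "rising",  eda_slope_level = "high",
                ibi_jitter_ms = 15,  pulse_range_level = "low",  pulse_slope_level = "low"),
    LAPV = list(eda_range_level = "high", eda_trend = "falling", eda_slope_level = "high",
                ibi_jitter_ms = 15,  pulse_range_level = "low",  pulse_slope_level = "low"),
    LANV = list(eda_range_level = "low",  eda_trend = "rising",  eda_slope_level = "low",
                ibi_jitter_ms = 150, pulse_range_level = "high", pulse_slope_level = "low"),
    HAPV = list(eda_range_level = "low",  eda_trend = "rising",  eda_slope_level = "low",
                ibi_jitter_ms = 150, pulse_range_level = "low",  pulse_slope_level = "high")
  )[[quadrant]]
  sc <- list(
    quadrant = quadrant,
    duration_s = duration_s,
    seed = as.integer(seed),
    eda_range_level = match.arg(eda_range_level %||% defaults$eda_range_level, c("low", "high")),
    eda_trend = match.arg(eda_trend %||% defaults$eda_trend, c("rising", "falling")),
    eda_slope_level = match.arg(eda_slope_level %||% defaults$eda_slope_level, c("low", "high")),
    ibi_jitter_ms = ibi_jitter_ms %||% defaults$ibi_jitter_ms,
    pulse_range_level = match.arg(pulse_range_level %||% defaults$pulse_range_level, c("low", "high")),
    pulse_slope_level = match.arg(pulse_slope_level %||% defaults$pulse_slope_level, c("low", "high")),
    base_ibi_ms = base_ibi_ms
  )
  if (!is.numeric(sc$duration_s) || sc$duration_s < 10) {
    invalid_argument("`duration_s` must be >= 10 s (one calculation window)")
  }
  if (sc$ibi_jitter_ms < 0) invalid_argument("`ibi_jitter_ms` must be >= 0")
  structure(sc, class = "quadrant_scenario")
}

# Fixed generator constants (arbitrary units). These ARE the study
# conditions the synthetic benchmark runs under; they are documented in
# the methods vignette and not meant to be tuned per run.
.synth_const <- list(
  eda_base = 10,
  eda_range = c(low = 2, high = 10),
  noise_frac = 0.02,           # additive Gaussian sigma as fraction of span
  pulse_amp = c(low = 1, high = 8),
  envelope_gain = c(low = 0, high = 0.6),  # relative amp rise over one window
  window_length_s = 10
)

# Per-window deterministic EDA shape on u in [0, 1].
.eda_shape <- function(u, trend, slope_level) {
  if (slope_level == "high") {
    if (trend == "rising") u else 1 - u
  } else {
    # tent: near-zero net slope, extrema order still follows `trend`
    if (trend == "rising") 1 - abs(2 * u - 1) else abs(2 * u - 1)
  }
}

#' Generate a synthetic electrodermal activity trace
#'
#' Tonic baseline plus a per-window deterministic deflection whose span,
#' extremum ordering and first-difference mean follow the scenario's
#' levels, plus additive Gaussian noise (sigma = 2% of the deflection
#' span). Windows of the standard 10-s length tile the segment exactly.
#'
#' @param scenario A [quadrant_scenario()].
#' @param fs Sampling rate in Hz (>= 10).
#' @return A [signal_trace()] with channel `"EDA"`.
#' @export
generate_eda <- function(scenario, fs = 100) {
  stopifnot(inherits(scenario, "quadrant_scenario"))
  if (fs < 10) invalid_argument("`fs` must be >= 10 Hz for EDA")
  if (scenario$duration_s <= 0) invalid_argument("non-positive duration")
  k <- .synth_const
  rng <- k$eda_range[[scenario$eda_range_level]]
  n_win <- round(k$window_length_s * fs)
  n_full <- round(scenario$duration_s * fs)
  n_windows <- ceiling(n_full / n_win)
  u <- (seq_len(n_win) - 1) / (n_win - 1)
  shape <- .eda_shape(u, scenario$eda_trend, scenario$eda_slope_level)
  det <- rep(k$eda_base + rng * shape, n_windows)[seq_len(n_full)]
  samples <- with_seed(sub_seed(scenario$seed, 101L), {
    det + stats::rnorm(n_full, sd = k$noise_frac * rng)
  })
  signal_trace(samples, fs = fs, channel = "EDA")
}

# One-beat pulse template on phase u in [0, 1]: main (systolic) wave,
# dicrotic anterior shoulder, dicrotic notch (the only local minimum
# between main and dicrotic waves, at u ~ 0.594) and the dicrotic wave
# itself (u ~ 0.699). Main-wave peak sits at u = 0.2361034868.
.ppg_template <- function(u) {
  exp(-(u - 0.23)^2 / (2 * 0.045^2)) +
    0.55 * exp(-(u - 0.36)^2 / (2 * 0.11^2)) +
    0.34 * exp(-(u - 0.70)^2 / (2 * 0.045^2))
}
.ppg_peak_phase <- 0.2361034868

#' Generate a synthetic pulse-wave (PPG) trace with ground-truth beats
#'
#' Beats are a fixed four-landmark template (main wave, dicrotic anterior
#' wave, dicrotic notch, dicrotic wave) placed at onsets whose spacing is
#' the base inter-beat interval plus Gaussian jitter with standard
#' deviation `ibi_jitter_ms` (clamped to 0.4-1.6 times the base so beats
#' never collide). Per-beat amplitude follows the scenario's range level
#' and, when `pulse_slope_level = "high"`, rises linearly within each
#' 10-s window so the beat-amplitude envelope has a positive slope.
#'
#' @param scenario A [quadrant_scenario()].
#' @param fs Sampling rate in Hz (>= 50, for beat-timing resolution).
#' @return A list with elements `trace` (a `"PPG"` [signal_trace()]),
#'   `beat_times` (ground-truth main-wave peak times, s), and `ibis_ms`
#'   (ground-truth inter-beat intervals, ms).
#' @export
generate_ppg <- function(scenario, fs = 100) {
  stopifnot(inherits(scenario, "quadrant_scenario"))
  if (fs < 50) invalid_argument("`fs` must be >= 50 Hz for PPG")
  if (scenario$base_ibi_ms <= 0) invalid_argument("base inter-beat interval must be positive")
  k <- .synth_const
  base_s <- scenario$base_ibi_ms / 1000
  amp0 <- k$pulse_amp[[scenario$pulse_range_level]]
  gain <- k$envelope_gain[[scenario$pulse_slope_level]]
  tpl_w <- 0.75 * base_s             # fixed template width: peak offset constant
  peak_off <- .ppg_peak_phase * tpl_w
  dur <- scenario$duration_s
  n <- round(dur * fs)

  with_seed(sub_seed(scenario$seed, 211L), {
    # beat onsets: last full template must end inside the segment
    onsets <- numeric(0)
    t <- 0.05
    while (t + tpl_w < dur) {
      onsets <- c(onsets, t)
      ibi <- base_s + stats::rnorm(1, sd = scenario$ibi_jitter_ms / 1000)
      ibi <- min(max(ibi, 0.4 * base_s), 1.6 * base_s)
      t <- t + ibi
    }
    if (length(onsets) < 2L) invalid_argument("segment too short for two beats")
    tt <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    wl <- k$window_length_s
    # envelope phase keyed to the main-wave PEAK time, so the rising
    # sawtooth restarts exactly at window boundaries as seen by a
    # window-local beat detector (no cross-boundary leakage)
    amps <- vapply(onsets, function(b) {
      env <- 1 + gain * (((b + peak_off) %% wl) / wl)
      amp0 * env * (1 + 0.02 * stats::rnorm(1))
    }, numeric(1))
    for (j in seq_along(onsets)) {
      i0 <- max(1L, floor(onsets[j] * fs) + 1L)
      i1 <- min(n, ceiling((onsets[j] + tpl_w) * fs) + 1L)
      idx <- i0:i1
      u <- (tt[idx] - onsets[j]) / tpl_w
      ok <- u >= 0 & u <= 1
      x[idx[ok]] <- x[idx[ok]] + amps[j] * .ppg_template(u[ok])
    }
    x <- x + stats::rnorm(n, sd = k$noise_frac * amp0)
    list(
      trace = signal_trace(x, fs = fs, channel = "PPG"),
      beat_times = onsets + peak_off,
      ibis_ms = diff(onsets) * 1000
    )
  })
}

#' Generate a labelled multi-segment synthetic session
#'
#' Concatenates one segment per scenario, keeping window boundaries
#' aligned to scenario boundaries, so each 10-s calculation window has a
#' ground-truth quadrant label.
#'
#' @param scenarios Non-empty list of [quadrant_scenario()] objects whose
#'   durations are whole multiples of `window_length_s`.
#' @param fs Sampling rate for both channels (Hz).
#' @param window_length_s Calculation-window length in seconds.
#' @return A `synthetic_session`: list with `eda` and `ppg` traces,
#'   per-window `labels`, ground-truth `beat_times` and `ibis_ms` (per
#'   segment), `fs`, and `window_length_s`.
#' @export
generate_session <- function(scenarios, fs = 100, window_length_s = 10) {
  if (!is.list(scenarios) || length(scenarios) == 0L ||
      inherits(scenarios, "quadrant_scenario")) {
    if (inherits(scenarios, "quadrant_scenario")) scenarios <- list(scenarios)
    else invalid_argument("`scenarios` must be a non-empty list of quadrant_scenario objects")
  }
  for (sc in scenarios) {
    if (!inherits(sc, "quadrant_scenario")) {
      invalid_argument("every element of `scenarios` must be a quadrant_scenario")
    }
    if (abs(sc$duration_s %% window_length_s) > 1e-9) {
      invalid_argument(sprintf(
        "scenario duration %g s is not a multiple of the %g s window",
        sc$duration_s, window_length_s
      ))
    }
  }
  eda <- numeric(0)
  ppg <- numeric(0)
  labels <- character(0)
  beat_times <- numeric(0)
  ibis_ms <- list()
  offset <- 0
  for (sc in scenarios) {
    e <- generate_eda(sc, fs = fs)
    p <- generate_ppg(sc, fs = fs)
    eda <- c(eda, e$samples)
    ppg <- c(ppg, p$trace$samples)
    labels <- c(labels, rep(sc$quadrant, sc$duration_s %/% window_length_s))
    beat_times <- c(beat_times, p$beat_times + offset)
    ibis_ms <- c(ibis_ms, list(p$ibis_ms))
    offset <- offset + sc$duration_s
  }
  structure(
    list(
      eda = signal_trace(eda, fs = fs, channel = "EDA"),
      ppg = signal_trace(ppg, fs = fs, channel = "PPG"),
      labels = labels,
      beat_times = beat_times,
      ibis_ms = ibis_ms,
      fs = fs,
      window_length_s = window_length_s
    ),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> %d windows of %g s @ %g Hz; labels: %s\n",
    length(x$labels), x$window_length_s, x$fs,
    paste(rle(x$labels)$values, "x", rle(x$labels)$lengths, collapse = ", ")
  ))
  invisible(x)
}

#' Default four-quadrant benchmark scenario sequence
#'
#' One segment per quadrant in the order HANV, LANV, LAPV, HAPV. The
#' order is chosen so that a four-window calibration prefix (the judge's
#' default) observes both the low and the high level of every judged
#' feature stream.
#'
#' @param windows_per_segment Number of 10-s windows per quadrant segment.
#' @param seed Session seed; each segment derives its own substream.
#' @return List of four [quadrant_scenario()] objects.
#' @export
default_scenarios <- function(windows_per_segment = 3, seed = 1L) {
  quads <- c("HANV", "LANV", "LAPV", "HAPV")
  lapply(seq_along(quads), function(i) {
    quadrant_scenario(
      quads[i],
      duration_s = windows_per_segment * 10,
      seed = sub_seed(seed, 1000L + i)
    )
  })
}
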