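#' Hardware calibration parameters for the skin-conductance channel
#'
#' The acquisition hardware injects a deterministic interference that is
#' removed with the rational correction
#' `f(r) = r - ((a + b * r) * c) / (d - r)`, where the constants are
#' device-specific values obtained by debugging the hardware. The default
#' mode is `"off"`: synthetic or already-calibrated data passes through
#' untouched.
#'
#' @param a,b,c,d Device constants (defaults 2014, 2, 10000, 512).
#' @param mode `"off"` (identity) or `"divide"` (apply the correction).
#' @return A `calibration_params` object.
#' @export
calibration_params <- function(a = 2014, b = 2, c = 10000, d = 512,
                               mode = c("off", "divide")) {
  structure(
    list(a = a, b = b, c = c, d = d, mode = match.arg(mode)),
    class = "calibration_params"
  )
}

#' Apply the hardware calibration transform to a raw trace
#'
#' @param trace A [signal_trace()] of raw device counts.
#' @param params A [calibration_params()]; with `mode = "off"` the trace is
#'   returned unchanged.
#' @return Calibrated [signal_trace()].
#' @export
calibrate_trace <- function(trace, params = calibration_params()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(params, "calibration_params"))
  if (params$mode == "off") return(trace)
  r <- trace$samples
  hit <- which(r == params$d)
  if (length(hit) > 0L) {
    stop_affect(
      sprintf(
        "calibration singularity: sample %d equals d = %g (zero denominator)",
        hit[1L], params$d
      ),
      "affectstream_singularity_error"
    )
  }
  f <- r - ((params$a + params$b * r) * params$c) / (params$d - r)
  signal_trace(f, fs = trace$fs, channel = trace$channel, t0 = trace$t0)
}

#' Analytic Butterworth low-pass magnitude response
#'
#' The classical frequency-distance form `H(D) = 1 / (1 + (D / D0)^(2n))`:
#' flat in the pass band, monotone to zero in the stop band, and exactly
#' 1/2 at the cutoff `D = D0`.
#'
#' @param D Frequency (or frequency distance), same units as `D0`.
#' @param D0 Cutoff (default 10, the pulse-wave channel's cutoff in Hz).
#' @param n Order parameter.
#' @return Response values in (0, 1].
#' @export
butterworth_gain <- function(D, D0 = 10, n = 1) {
  1 / (1 + (D / D0)^(2 * n))
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Realizes the Butterworth low-pass as a digital IIR filter applied
#' forward and backward (`signal::filtfilt`), giving zero phase shift so
#' fiducial timing is preserved. Default cutoff 10 Hz, order 4.
#'
#' @param trace A [signal_trace()].
#' @param cutoff_hz Low-pass cutoff in Hz (must be below Nyquist).
#' @param order Filter order (>= 1).
#' @return Filtered [signal_trace()].
#' @export
lowpass_filter <- function(trace, cutoff_hz = 10, order = 4) {
  stopifnot(inherits(trace, "signal_trace"))
  if (order < 1) invalid_argument("`order` must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= trace$fs / 2) {
    invalid_argument(sprintf(
      "cutoff %g Hz must lie in (0, Nyquist = %g Hz)", cutoff_hz, trace$fs / 2
    ))
  }
  bf <- signal::butter(order, cutoff_hz / (trace$fs / 2), type = "low")
  x <- trace$samples
  n <- length(x)
  # odd-reflection padding suppresses the startup transients of the
  # forward-backward pass (value- and slope-continuous extension)
  pad <- min(n - 1L, max(9L, 3L * order * ceiling(trace$fs / cutoff_hz)))
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(bf, ext)[(pad + 1L):(pad + n)]
  signal_trace(y, fs = trace$fs, channel = trace$channel, t0 = trace$t0)
}

#' Min-max normalization to the 0-100 range
#'
#' `y = 100 * (x - min) / (max - min)`. Both bounds are attained; a
#' constant segment has no span to normalize and raises a
#' degenerate-segment error so the caller can skip the window.
#'
#' @param x Numeric vector, [signal_trace()] or `signal_window`.
#' @return Same shape as the input, values in \[0, 100\].
#' @export
normalize_0_100 <- function(x) {
  if (inherits(x, "signal_trace")) {
    return(signal_trace(normalize_0_100(x$samples),
                        fs = x$fs, channel = x$channel, t0 = x$t0))
  }
  if (inherits(x, "signal_window")) {
    w <- x
    w$samples <- normalize_0_100(w$samples)
    w$x_min <- 0
    w$x_max <- 100
    return(w)
  }
  v <- as.numeric(x)
  lo <- min(v)
  hi <- max(v)
  # relative tolerance so numerically-constant segments (e.g. a constant
  # after a float round trip) are flagged too
  if (hi - lo <= 1e-12 * max(1, abs(hi), abs(lo))) {
    stop_affect("constant segment: min-max normalization undefined",
                "affectstream_degenerate_segment")
  }
  100 * (v - lo) / (hi - lo)
}

#' Preprocess a two-channel session
#'
#' The standard cleaning chain: optional hardware calibration of the EDA
#' channel, three-level wavelet denoising of EDA, zero-phase Butterworth
#' low-pass (10 Hz) of PPG, then min-max normalization of each whole trace
#' to 0-100. Normalization is applied per trace, not per window, so
#' between-window amplitude differences -- the material the rule tree
#' works with -- survive; all downstream judgments are invariant to this
#' choice because thresholds are re-normalized per feature stream.
#'
#' @param session A `synthetic_session` or a list with `eda` and `ppg`
#'   [signal_trace()] elements.
#' @param calibration [calibration_params()] for the EDA channel.
#' @param wavelet_levels,wavelet_threshold,wavelet_mode Passed to
#'   [wavelet_denoise()].
#' @param cutoff_hz,filter_order Passed to [lowpass_filter()] (PPG only).
#' @param filter_both Also low-pass the EDA channel (default `FALSE`).
#' @return The session with cleaned `eda` and `ppg` traces.
#' @export
preprocess_session <- function(session,
                               calibration = calibration_params(),
                               wavelet_levels = 3,
                               wavelet_threshold = "universal",
                               wavelet_mode = "soft",
                               cutoff_hz = 10,
                               filter_order = 4,
                               filter_both = FALSE) {
  eda <- calibrate_trace(session$eda, calibration)
  eda <- wavelet_denoise(eda, levels = wavelet_levels,
                         threshold = wavelet_threshold, mode = wavelet_mode)
  if (filter_both) eda <- lowpass_filter(eda, cutoff_hz, filter_order)
  ppg <- lowpass_filter(session$ppg, cutoff_hz, filter_order)
  session$eda <- normalize_0_100(eda)
  session$ppg <- normalize_0_100(ppg)
  session
}
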