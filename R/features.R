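#' Detect pulse-wave beats and their fiducial landmarks
#'
#' Main-wave (systolic) peaks are located by prominence-style peak picking
#' (height above half the window span, minimum spacing 0.35 s). Between
#' each pair of successive main-wave peaks, the dicrotic wave is the
#' highest interior local maximum, the dicrotic notch is the lowest local
#' minimum between the main and dicrotic waves, and the dicrotic anterior
#' wave is the flattest shoulder (smallest absolute slope) between the
#' main wave and the notch. The waveform-period start (pulse foot) is the
#' minimum preceding each main-wave peak.
#'
#' @param x A `signal_window`, [signal_trace()], or numeric vector.
#' @param fs Sampling rate in Hz (taken from `x` when it carries one).
#' @return A data frame with one row per beat: times (s, relative to the
#'   start of `x`) and amplitudes of the four landmarks, `period_s`,
#'   `t_onset_to_main_peak_s` and `t_onset_to_notch_s`. The last beat has
#'   `NA` for the landmarks that need the following peak.
#' @export
detect_beats <- function(x, fs = NULL) {
  if (inherits(x, "signal_window") || inherits(x, "signal_trace")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) invalid_argument("`fs` required when `x` is a bare vector")
  x <- as.numeric(x)
  span <- max(x) - min(x)
  if (span <= 0) {
    stop_affect("flat signal: no detectable beats", "affectstream_insufficient_beats")
  }
  pk <- pracma::findpeaks(
    x,
    minpeakheight = min(x) + 0.5 * span,
    minpeakdistance = max(1L, round(0.35 * fs))
  )
  if (is.null(pk) || nrow(pk) < 2L) {
    stop_affect("fewer than 2 detectable beats in scope",
                "affectstream_insufficient_beats")
  }
  ord <- order(pk[, 2L])
  peak_i <- pk[ord, 2L]
  peak_v <- pk[ord, 1L]
  nb <- length(peak_i)

  local_max <- function(v) which(diff(sign(diff(v))) < 0) + 1L
  local_min <- function(v) which(diff(sign(diff(v))) > 0) + 1L

  out <- data.frame(
    beat = seq_len(nb),
    t_main = (peak_i - 1L) / fs,
    amp_main = peak_v,
    t_anterior = NA_real_, amp_anterior = NA_real_,
    t_notch = NA_real_, amp_notch = NA_real_,
    t_dicrotic = NA_real_, amp_dicrotic = NA_real_,
    t_onset = NA_real_,
    period_s = NA_real_,
    t_onset_to_main_peak_s = NA_real_,
    t_onset_to_notch_s = NA_real_
  )

  for (j in seq_len(nb)) {
    # pulse foot: minimum between previous peak (or start) and this peak
    lo <- if (j == 1L) 1L else peak_i[j - 1L]
    seg <- x[lo:peak_i[j]]
    out$t_onset[j] <- (lo + which.min(seg) - 2L) / fs
    out$t_onset_to_main_peak_s[j] <- out$t_main[j] - out$t_onset[j]
    if (j == nb) next
    gap <- peak_i[j + 1L] - peak_i[j]
    out$period_s[j] <- gap / fs
    i0 <- peak_i[j] + max(1L, round(0.10 * gap))
    i1 <- peak_i[j] + round(0.85 * gap)
    sub <- x[i0:i1]
    lm <- local_max(sub)
    if (length(lm) == 0L) next
    dic <- i0 - 1L + lm[which.max(sub[lm])]
    between <- x[peak_i[j]:dic]
    mins <- local_min(between)
    notch_rel <- if (length(mins) > 0L) mins[which.min(between[mins])] else which.min(between)
    notch <- peak_i[j] + notch_rel - 1L
    out$t_dicrotic[j] <- (dic - 1L) / fs
    out$amp_dicrotic[j] <- x[dic]
    out$t_notch[j] <- (notch - 1L) / fs
    out$amp_notch[j] <- x[notch]
    out$t_onset_to_notch_s[j] <- out$t_notch[j] - out$t_onset[j]
    # anterior shoulder: flattest point strictly between main peak and notch
    if (notch - peak_i[j] > 2L) {
      ii <- (peak_i[j] + 1L):(notch - 1L)
      slopes <- abs(diff(x)[ii])  # diff(x)[i] is slope between i and i+1
      ant <- ii[which.min(slopes)]
      out$t_anterior[j] <- (ant - 1L) / fs
      out$amp_anterior[j] <- x[ant]
    }
  }
  out
}

#' Inter-beat intervals from detected fiducials
#'
#' Intervals are measured between successive main-wave peaks, in ms.
#'
#' @param fiducials Data frame from [detect_beats()].
#' @return Numeric vector of intervals (ms), length `nrow(fiducials) - 1`.
#' @export
beat_intervals_ms <- function(fiducials) {
  diff(fiducials$t_main) * 1000
}

#' BpNN50: fraction of successive inter-beat-interval differences > 50 ms
#'
#' The pulse-wave analogue of the heart-rate-variability pNN50 statistic:
#' `count(|x[i+1] - x[i]| > threshold) / (N - 1)` over `N` successive
#' inter-beat intervals. The inequality is strict, so a difference of
#' exactly 50 ms does not count. `signed_diffs = TRUE` drops the absolute
#' value and counts only positive differences exceeding the threshold.
#'
#' @param intervals_ms Inter-beat intervals in milliseconds (length >= 2).
#' @param threshold_ms Difference threshold in ms (default 50).
#' @param signed_diffs Count signed rather than absolute differences.
#' @return Fraction in \[0, 1\].
#' @export
bpnn50 <- function(intervals_ms, threshold_ms = 50, signed_diffs = FALSE) {
  if (length(intervals_ms) < 2L) {
    invalid_argument("need at least 2 inter-beat intervals")
  }
  d <- diff(intervals_ms)
  if (!signed_diffs) d <- abs(d)
  mean(d > threshold_ms)
}

#' Range of a window: max(x) - min(x)
#'
#' @param x Numeric vector or `signal_window` (non-empty).
#' @return Non-negative scalar.
#' @export
signal_range <- function(x) {
  if (inherits(x, "signal_window")) return(x$x_max - x$x_min)
  if (length(x) == 0L) invalid_argument("empty window")
  max(x) - min(x)
}

#' Mean first-order difference of a window
#'
#' `(1 / (N - 1)) * sum(x[i+1] - x[i])`, a signed slope proxy; by
#' telescoping it equals `(x[N] - x[1]) / (N - 1)` exactly.
#'
#' @param x Numeric vector of length >= 2 (or `signal_window`).
#' @return Signed scalar in signal units per sample.
#' @export
one_d_mean <- function(x) {
  if (inherits(x, "signal_window")) x <- x$samples
  n <- length(x)
  if (n < 2L) invalid_argument("need at least 2 samples")
  mean(diff(x))
}
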