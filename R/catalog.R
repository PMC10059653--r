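# Per-window feature catalogue. The judged optimal set (BpNN50, EDA range,
# EDA 1dmean) lives inside a larger catalogue of 24 + 18 time-domain,
# 8 + 8 frequency-domain and 7 + 10 physiological descriptors, so the
# selection procedure has a realistic dimensionality to reduce.

.time_stats_shared <- c(
  "mean", "sd", "median", "min", "max", "range", "iqr", "rms",
  "skewness", "kurtosis", "1dmean", "abs1dmean", "sd1d", "sd2d",
  "zerocross", "p25", "p75", "linslope"
)
.time_stats_eda_extra <- c("max1d", "min1d", "2dmean", "abs2dmean", "p10", "p90")
.freq_stats <- c(
  "power_total", "bp_slow", "bp_lf", "bp_mf", "bp_hf",
  "spec_centroid", "spec_entropy", "peak_freq"
)
.physio_eda <- c(
  "scr_count", "scr_amp_mean", "scr_rise_mean", "tonic_level",
  "phasic_sd", "auc", "max_deflection"
)
.physio_ppg <- c(
  "ibi_mean", "sdnn", "rmssd", "bpnn50", "amp_main_mean", "amp_1dmean",
  "notch_ratio_mean", "dicrotic_ratio_mean", "t_notch_mean", "t_peak_mean"
)

#' The per-window feature catalogue
#'
#' Time-domain descriptors (24 for the EDA channel, 18 for the pulse-wave
#' channel), frequency-domain descriptors computed with one shared
#' implementation for both channels (8 each), and physiological
#' descriptors (7 EDA, 10 pulse). Feature columns produced by
#' [extract_features()] are named `<channel>_<descriptor>`.
#'
#' @return A data frame with columns `name`, `channel`, `family`.
#' @export
feature_catalog <- function() {
  rbind(
    data.frame(name = paste0("eda_", c(.time_stats_shared, .time_stats_eda_extra)),
               channel = "EDA", family = "time_domain"),
    data.frame(name = paste0("ppg_", .time_stats_shared),
               channel = "PPG", family = "time_domain"),
    data.frame(name = paste0("eda_", .freq_stats),
               channel = "EDA", family = "frequency_domain"),
    data.frame(name = paste0("ppg_", .freq_stats),
               channel = "PPG", family = "frequency_domain"),
    data.frame(name = paste0("eda_", .physio_eda),
               channel = "EDA", family = "physiological"),
    data.frame(name = paste0("ppg_", .physio_ppg),
               channel = "PPG", family = "physiological")
  )
}

.time_features <- function(x, extra = FALSE) {
  n <- length(x)
  d1 <- diff(x)
  d2 <- diff(d1)
  tctr <- seq_len(n) - (n + 1) / 2
  xc <- x - mean(x)
  out <- c(
    mean = mean(x), sd = stats::sd(x), median = stats::median(x),
    min = min(x), max = max(x), range = max(x) - min(x),
    iqr = stats::IQR(x), rms = sqrt(mean(x^2)),
    skewness = e1071::skewness(x), kurtosis = e1071::kurtosis(x),
    "1dmean" = mean(d1), abs1dmean = mean(abs(d1)), sd1d = stats::sd(d1),
    sd2d = stats::sd(d2),
    zerocross = sum(diff(sign(xc)) != 0),
    p25 = unname(stats::quantile(x, 0.25)), p75 = unname(stats::quantile(x, 0.75)),
    linslope = sum(tctr * xc) / sum(tctr^2)
  )
  if (extra) {
    out <- c(out, c(
      max1d = max(d1), min1d = min(d1), "2dmean" = mean(d2),
      abs2dmean = mean(abs(d2)),
      p10 = unname(stats::quantile(x, 0.10)), p90 = unname(stats::quantile(x, 0.90))
    ))
  }
  out
}

# One shared spectral implementation for both channels: raw periodogram of
# the mean-removed window, band edges chosen around typical EDA phasic
# (< 0.5 Hz) and cardiac (~1 Hz fundamental plus harmonics) content.
.freq_features <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n
  j <- 2:(n %/% 2 + 1)
  f <- (j - 1) * fs / n
  p <- p[j]
  tot <- sum(p)
  band <- function(lo, hi) sum(p[f >= lo & f < hi])
  q <- p / tot
  c(
    power_total = tot,
    bp_slow = band(0, 0.5), bp_lf = band(0.5, 1.5),
    bp_mf = band(1.5, 3), bp_hf = band(3, 5),
    spec_centroid = sum(f * p) / tot,
    spec_entropy = -sum(q[q > 0] * log(q[q > 0])) / log(length(q)),
    peak_freq = f[which.max(p)]
  )
}

.eda_physio_features <- function(x, fs) {
  span <- max(x) - min(x)
  tonic <- unname(stats::quantile(x, 0.10))
  pk <- pracma::findpeaks(
    x,
    minpeakheight = tonic + 0.1 * span,
    minpeakdistance = max(1L, round(1 * fs))
  )
  if (is.null(pk)) {
    scr_count <- 0
    scr_amp <- 0
    scr_rise <- 0
  } else {
    scr_count <- nrow(pk)
    scr_amp <- mean(pk[, 1] - tonic)
    # mean rise slope from the ascent start found by findpeaks
    rise <- (pk[, 1] - x[pk[, 3]]) / pmax(pk[, 2] - pk[, 3], 1) * fs
    scr_rise <- mean(rise)
  }
  tctr <- seq_along(x) - (length(x) + 1) / 2
  slope <- sum(tctr * (x - mean(x))) / sum(tctr^2)
  detr <- x - mean(x) - slope * tctr
  c(
    scr_count = scr_count, scr_amp_mean = scr_amp, scr_rise_mean = scr_rise,
    tonic_level = tonic, phasic_sd = stats::sd(detr),
    auc = mean(x - min(x)), max_deflection = max(x) - tonic
  )
}

.ppg_physio_features <- function(x, fs) {
  empty <- stats::setNames(rep(NA_real_, length(.physio_ppg)), .physio_ppg)
  fid <- tryCatch(detect_beats(x, fs = fs), affectstream_error = function(e) NULL)
  if (is.null(fid)) return(empty)
  ibis <- beat_intervals_ms(fid)
  if (length(ibis) < 2L) return(empty)
  amps <- fid$amp_main
  c(
    ibi_mean = mean(ibis), sdnn = stats::sd(ibis),
    rmssd = sqrt(mean(diff(ibis)^2)),
    bpnn50 = bpnn50(ibis),
    amp_main_mean = mean(amps),
    amp_1dmean = one_d_mean(amps),
    notch_ratio_mean = mean(fid$amp_notch / fid$amp_main, na.rm = TRUE),
    dicrotic_ratio_mean = mean(fid$amp_dicrotic / fid$amp_main, na.rm = TRUE),
    t_notch_mean = mean(fid$t_onset_to_notch_s, na.rm = TRUE),
    t_peak_mean = mean(fid$t_onset_to_main_peak_s, na.rm = TRUE)
  )
}

.channel_features <- function(x, fs, channel) {
  pre <- if (channel == "EDA") "eda_" else "ppg_"
  if (max(x) - min(x) <= 0) {
    # degenerate window: features flagged absent, not zero
    nm <- feature_catalog()
    nm <- nm$name[startsWith(nm$name, pre)]
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  tf <- .time_features(x, extra = channel == "EDA")
  ff <- .freq_features(x, fs)
  pf <- if (channel == "EDA") .eda_physio_features(x, fs) else .ppg_physio_features(x, fs)
  out <- c(tf, ff, pf)
  stats::setNames(out, paste0(pre, names(out)))
}

#' Extract the full feature catalogue per calculation window
#'
#' Segments the aligned EDA and PPG traces into 10-s windows and computes
#' one value per catalogue feature per window. Pulse-derived features are
#' `NA` (absent, not zero) in windows without at least two detectable
#' beats; all features of a degenerate (constant) window are `NA`.
#' Window bookkeeping columns (`window`, `eda_n_min`, `eda_n_max`) are
#' included but are not catalogue features.
#'
#' @param x A `synthetic_session`, any list with `eda` and `ppg`
#'   [signal_trace()] elements, or an EDA [signal_trace()] when `ppg`
#'   is supplied separately.
#' @param ppg PPG [signal_trace()] (when `x` is the EDA trace).
#' @param window_length_s Window length in seconds (default 10).
#' @return A data frame, one row per window, one column per feature.
#' @export
extract_features <- function(x, ppg = NULL, window_length_s = 10) {
  if (is.list(x) && !inherits(x, "signal_trace") &&
      !is.null(x$eda) && !is.null(x$ppg)) {
    eda <- x$eda
    ppg <- x$ppg
    window_length_s <- x$window_length_s %||% window_length_s
  } else {
    eda <- x
    if (is.null(ppg)) invalid_argument("supply `ppg` when `x` is a single trace")
  }
  ew <- segment_windows(eda, window_length_s)
  pw <- segment_windows(ppg, window_length_s)
  n <- min(length(ew), length(pw))
  rows <- lapply(seq_len(n), function(i) {
    c(
      window = ew[[i]]$index,
      eda_n_min = ew[[i]]$n_min,
      eda_n_max = ew[[i]]$n_max,
      .channel_features(ew[[i]]$samples, eda$fs, "EDA"),
      .channel_features(pw[[i]]$samples, ppg$fs, "PPG")
    )
  })
  df <- as.data.frame(do.call(rbind, rows))
  attr(df, "catalog") <- feature_catalog()
  df
}
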