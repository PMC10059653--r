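# Periodized Mallat pyramid with Daubechies-4 (8-tap) filters.
#
# Written in-package because no wavelet library ships with the R stack this
# package targets. The decomposition is the standard orthogonal DWT with
# circular boundary handling; odd-length vectors are extended by repeating
# the last sample (recorded and trimmed on reconstruction), so any input
# length round-trips exactly.

# db4 analysis low-pass filter (orthonormal: sum h = sqrt(2), sum h^2 = 1).
.db4_lo <- c(
  -1.05974017850690317e-02,
   3.28830116668851966e-02,
   3.08413818355607640e-02,
  -1.87034811719093086e-01,
  -2.79837694168598543e-02,
   6.30880767929858921e-01,
   7.14846570552915672e-01,
   2.30377813308896506e-01
)

# quadrature-mirror high-pass: g[k] = (-1)^k h[L-1-k]  (0-based k)
.db4_hi <- rev(.db4_lo) * (-1)^(seq_along(.db4_lo) - 1)

# circular filter-and-decimate: a[m] = sum_k f[k] x[(2(m-1) + k - 1) mod N + 1]
.dwt_step <- function(x, f) {
  n <- length(x)
  m <- n %/% 2L
  idx <- outer(2L * (seq_len(m) - 1L), seq_along(f) - 1L, "+") %% n + 1L
  drop(matrix(x[idx], nrow = m) %*% f)
}

# adjoint of the analysis step: x[n] = sum_m a[m] f[(n - 2m) mod N]
.idwt_step <- function(a, d, lo, hi) {
  m <- length(a)
  n <- 2L * m
  x <- numeric(n)
  for (k in seq_along(lo)) {
    pos <- (2L * (seq_len(m) - 1L) + (k - 1L)) %% n + 1L
    contrib <- a * lo[k] + d * hi[k]
    x[pos] <- x[pos] + contrib
  }
  x
}

# Multi-level analysis. Returns approximation, detail list (finest first)
# and the pre-padding length at each level.
.dwt <- function(x, levels) {
  details <- vector("list", levels)
  lens <- integer(levels)
  a <- x
  for (l in seq_len(levels)) {
    lens[l] <- length(a)
    if (length(a) %% 2L == 1L) a <- c(a, a[length(a)])
    details[[l]] <- .dwt_step(a, .db4_hi)
    a <- .dwt_step(a, .db4_lo)
  }
  list(approx = a, details = details, lens = lens)
}

.idwt <- function(dec) {
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    a <- .idwt_step(a, dec$details[[l]], .db4_lo, .db4_hi)
    a <- a[seq_len(dec$lens[l])]
  }
  a
}

#' Wavelet denoising of a signal trace
#'
#' Three-level (by default) orthogonal db4 decomposition, thresholding of
#' the detail coefficients, and reconstruction. The default threshold is
#' the universal rule `sigma * sqrt(2 log N)` with `sigma` estimated from
#' the finest-level details by the median-absolute-deviation rule; soft
#' thresholding is the default shrinkage. With `threshold = 0` the
#' transform round-trips and the input is returned unchanged up to
#' floating-point error.
#'
#' @param trace A [signal_trace()] (or bare numeric vector).
#' @param levels Decomposition depth (default 3).
#' @param threshold `"universal"` or a non-negative number (same units as
#'   the signal) applied to every detail level.
#' @param mode `"soft"` or `"hard"` thresholding.
#' @return Denoised trace (same class and length as the input).
#' @export
wavelet_denoise <- function(trace, levels = 3, threshold = "universal",
                            mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  x <- if (inherits(trace, "signal_trace")) trace$samples else as.numeric(trace)
  if (levels < 1) invalid_argument("`levels` must be >= 1")
  if (length(x) < 2^levels) {
    invalid_argument(sprintf(
      "trace of %d samples too short for %d-level decomposition", length(x), levels
    ))
  }
  dec <- .dwt(x, levels)
  if (identical(threshold, "universal")) {
    sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(length(x)))
  } else {
    thr <- as.numeric(threshold)
    if (is.na(thr) || thr < 0) invalid_argument("`threshold` must be \"universal\" or >= 0")
  }
  dec$details <- lapply(dec$details, function(d) {
    if (mode == "soft") sign(d) * pmax(abs(d) - thr, 0) else d * (abs(d) > thr)
  })
  y <- .idwt(dec)
  if (inherits(trace, "signal_trace")) {
    signal_trace(y, fs = trace$fs, channel = trace$channel, t0 = trace$t0)
  } else {
    y
  }
}
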