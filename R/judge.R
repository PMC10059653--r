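#' Valence-arousal quadrants
#'
#' The four quadrants of the valence-arousal plane plus the `UNDECIDED`
#' outcome emitted when no rule fires: HAPV (high arousal, positive
#' valence), HANV (high arousal, negative valence), LANV (low arousal,
#' negative valence), LAPV (low arousal, positive valence).
#'
#' @format Character vector of the five decision labels.
#' @export
quadrant_levels <- c("HAPV", "HANV", "LANV", "LAPV", "UNDECIDED")

#' Arousal/valence signs of a quadrant
#' @param quadrant Quadrant label.
#' @return Named numeric vector `c(arousal = , valence = )` (+1/-1), or
#'   `NA`s for `UNDECIDED`.
#' @export
quadrant_signs <- function(quadrant) {
  switch(match.arg(quadrant, quadrant_levels),
    HAPV = c(arousal = 1, valence = 1),
    HANV = c(arousal = 1, valence = -1),
    LANV = c(arousal = -1, valence = -1),
    LAPV = c(arousal = -1, valence = 1),
    UNDECIDED = c(arousal = NA_real_, valence = NA_real_)
  )
}

#' Compute the normalized adaptive threshold x_th for a feature stream
#'
#' The threshold of a feature stream is the mean of its min-max-normalized
#' values over a reference span:
#' `x_th = sum((x - x_min) / (x_max - x_min)) / n`.
#' The normalization parameters (`x_min`, `x_max`) are frozen from the
#' reference span; values observed later are normalized with the same
#' parameters and clipped to \[0, 1\], which keeps the decision stream
#' causal. `x_th` is invariant to positive affine rescaling of the raw
#' feature.
#'
#' @param values Numeric feature values over windows.
#' @param reference Indices of the reference (calibration) span; defaults
#'   to the whole stream. Needs >= 2 distinct finite values.
#' @param name,channel Optional labels carried along for reporting.
#' @return A `feature_stream`: list with `values`, `normalized`, `x_min`,
#'   `x_max`, `x_th`, `reference`.
#' @export
compute_threshold <- function(values, reference = seq_along(values),
                              name = NA_character_, channel = NA_character_) {
  ref <- values[reference]
  ref <- ref[is.finite(ref)]
  if (length(ref) < 2L || max(ref) <= min(ref)) {
    stop_affect(
      sprintf("degenerate threshold for %s: reference span has < 2 distinct values",
              name),
      "affectstream_degenerate_threshold"
    )
  }
  x_min <- min(ref)
  x_max <- max(ref)
  normalized <- pmin(pmax((values - x_min) / (x_max - x_min), 0), 1)
  structure(
    list(
      name = name, channel = channel, values = values,
      normalized = normalized, x_min = x_min, x_max = x_max,
      x_th = mean(pmin(pmax((ref - x_min) / (x_max - x_min), 0), 1)),
      reference = reference
    ),
    class = "feature_stream"
  )
}

#' @export
print.feature_stream <- function(x, ...) {
  cat(sprintf(
    "<feature_stream> %s: %d values, x_th = %.4f (span [%.4g, %.4g])\n",
    x$name, length(x$values), x$x_th, x$x_min, x$x_max
  ))
  invisible(x)
}

# The rule tree, evaluated on one window's normalized features.
#
# EDA branch:   range > x_th  ->  n_max <= n_min ? LAPV
#                                 : 1dmean > x_th ? HANV : (nothing)
# Pulse branch: BpNN50 > x_th ->  range > x_th ? LANV
#                                 : 1dmean > x_th ? HAPV : (nothing)
#
# All comparisons are strict; boundary equality falls to the "otherwise"
# arm. If both branches yield a quadrant the conflict is resolved by the
# fixed priority HANV > LANV > LAPV > HAPV (negative-valence states drive
# game adaptation; HAPV triggers nothing).
.judge_priority <- c("HANV", "LANV", "LAPV", "HAPV")

.trace_step <- function(test, lhs, rhs, outcome) {
  list(test = test, lhs = lhs, rhs = rhs, outcome = outcome)
}

#' Judge one calculation window
#'
#' Applies the rule tree to one window's normalized feature values and
#' thresholds. Features are supplied already normalized to \[0, 1\] on
#' their stream's reference span (see [compute_threshold()]).
#'
#' @param features Named list/vector with entries `eda_range`,
#'   `eda_1dmean`, `ppg_bpnn50`, `ppg_range`, `ppg_1dmean` (normalized;
#'   `NA` allowed and treated as an unusable branch) and the EDA window's
#'   `n_max`, `n_min` sample indices.
#' @param thresholds Named list/vector of `x_th` values for the same five
#'   streams.
#' @param window Window ordinal carried into the decision.
#' @return An `emotion_decision`: list with `window`, `quadrant`,
#'   `branch` (`"eda"`, `"pulse"`, or `NA`), `partial` flag and the
#'   ordered `rule_trace`.
#' @export
judge_window <- function(features, thresholds, window = NA_integer_) {
  f <- as.list(features)
  th <- as.list(thresholds)
  trace <- list()
  candidates <- character(0)
  branches <- character(0)

  eda_ok <- !is.na(f$eda_range) && !is.na(th$eda_range)
  if (eda_ok) {
    g <- f$eda_range > th$eda_range
    trace <- c(trace, list(.trace_step("eda_range > x_th", f$eda_range, th$eda_range, g)))
    if (g) {
      rising <- f$n_max > f$n_min
      trace <- c(trace, list(.trace_step("n_max > n_min", f$n_max, f$n_min, rising)))
      if (!rising) {
        candidates <- c(candidates, "LAPV")
        branches <- c(branches, "eda")
      } else if (!is.na(f$eda_1dmean) && !is.na(th$eda_1dmean)) {
        h <- f$eda_1dmean > th$eda_1dmean
        trace <- c(trace, list(.trace_step("eda_1dmean > x_th", f$eda_1dmean, th$eda_1dmean, h)))
        if (h) {
          candidates <- c(candidates, "HANV")
          branches <- c(branches, "eda")
        }
      }
    }
  }

  pulse_ok <- !is.na(f$ppg_bpnn50) && !is.na(th$ppg_bpnn50)
  if (pulse_ok) {
    g <- f$ppg_bpnn50 > th$ppg_bpnn50
    trace <- c(trace, list(.trace_step("bpnn50 > x_th", f$ppg_bpnn50, th$ppg_bpnn50, g)))
    if (g) {
      if (!is.na(f$ppg_range) && !is.na(th$ppg_range)) {
        r <- f$ppg_range > th$ppg_range
        trace <- c(trace, list(.trace_step("ppg_range > x_th", f$ppg_range, th$ppg_range, r)))
        if (r) {
          candidates <- c(candidates, "LANV")
          branches <- c(branches, "pulse")
        } else if (!is.na(f$ppg_1dmean) && !is.na(th$ppg_1dmean)) {
          h <- f$ppg_1dmean > th$ppg_1dmean
          trace <- c(trace, list(.trace_step("ppg_1dmean > x_th", f$ppg_1dmean, th$ppg_1dmean, h)))
          if (h) {
            candidates <- c(candidates, "HAPV")
            branches <- c(branches, "pulse")
          }
        }
      }
    }
  }

  if (length(candidates) == 0L) {
    quadrant <- "UNDECIDED"
    branch <- NA_character_
  } else {
    pick <- .judge_priority[.judge_priority %in% candidates][1L]
    branch <- branches[match(pick, candidates)]
    quadrant <- pick
    if (length(candidates) > 1L) {
      trace <- c(trace, list(.trace_step(
        "priority HANV > LANV > LAPV > HAPV",
        paste(candidates, collapse = ","), NA, pick
      )))
    }
  }
  structure(
    list(
      window = window, quadrant = quadrant, branch = branch,
      partial = !eda_ok || !pulse_ok, rule_trace = trace
    ),
    class = "emotion_decision"
  )
}

#' @export
print.emotion_decision <- function(x, ...) {
  cat(sprintf("<emotion_decision> window %s: %s (branch %s)\n",
              x$window, x$quadrant, x$branch %||% NA))
  for (s in x$rule_trace) {
    cat(sprintf("  %-28s %8.4g vs %-8.4g -> %s\n",
                s$test, as.numeric(s$lhs), as.numeric(s$rhs), s$outcome))
  }
  invisible(x)
}

# The five judged feature streams, by feature-table column. The pulse
# "1dmean" stream is the first-difference mean of the per-beat main-wave
# amplitude series (pulse-envelope slope); see the methods vignette.
.judged_streams <- c(
  eda_range = "eda_range", eda_1dmean = "eda_1dmean",
  ppg_bpnn50 = "ppg_bpnn50", ppg_range = "ppg_range",
  ppg_1dmean = "ppg_amp_1dmean"
)

#' Judge every window of a session
#'
#' Runs the full decision pipeline on a (preprocessed) session: extracts
#' the judged feature streams per 10-s window, freezes each stream's
#' normalization and threshold on a calibration prefix, and applies the
#' rule tree to every subsequent window. Calibration windows are emitted
#' as `UNDECIDED` with `calibration = TRUE`.
#'
#' A stream whose calibration values are constant cannot be normalized;
#' its branch tests are skipped (with a warning) rather than failing the
#' whole session. If every stream is degenerate -- e.g. constant input
#' signals -- a degenerate-threshold error is raised.
#'
#' @param session A `synthetic_session` or list with `eda`/`ppg` traces
#'   (already preprocessed; see [preprocess_session()]).
#' @param calibration_windows Number of leading windows used only to seed
#'   thresholds (default 4).
#' @param features Optional precomputed [extract_features()] table.
#' @return An `emotion_decisions` data frame (`window`, `quadrant`,
#'   `branch`, `calibration`, `partial`) with the per-window decision
#'   objects in `attr(, "decisions")` and the streams in
#'   `attr(, "streams")`.
#' @export
judge_session <- function(session, calibration_windows = 4, features = NULL) {
  if (is.null(features)) features <- extract_features(session)
  n <- nrow(features)
  if (n < calibration_windows + 1) {
    invalid_argument(sprintf(
      "session has %d windows; need more than calibration_windows = %d",
      n, calibration_windows
    ))
  }
  ref <- seq_len(calibration_windows)
  streams <- list()
  for (nm in names(.judged_streams)) {
    streams[[nm]] <- tryCatch(
      compute_threshold(features[[.judged_streams[[nm]]]], reference = ref, name = nm),
      affectstream_degenerate_threshold = function(e) {
        warning(sprintf("stream %s degenerate over calibration span; its tests are skipped", nm),
                call. = FALSE)
        NULL
      }
    )
  }
  if (all(vapply(streams, is.null, logical(1)))) {
    stop_affect("all judged feature streams are degenerate over the calibration span",
                "affectstream_degenerate_threshold")
  }
  val <- function(nm, i) if (is.null(streams[[nm]])) NA_real_ else streams[[nm]]$normalized[i]
  th <- lapply(streams, function(s) if (is.null(s)) NA_real_ else s$x_th)
  decisions <- lapply(seq_len(n), function(i) {
    if (i <= calibration_windows) {
      return(structure(
        list(window = features$window[i], quadrant = "UNDECIDED", branch = NA_character_,
             partial = FALSE, rule_trace = list(), calibration = TRUE),
        class = "emotion_decision"
      ))
    }
    d <- judge_window(
      features = list(
        eda_range = val("eda_range", i), eda_1dmean = val("eda_1dmean", i),
        ppg_bpnn50 = val("ppg_bpnn50", i), ppg_range = val("ppg_range", i),
        ppg_1dmean = val("ppg_1dmean", i),
        n_max = features$eda_n_max[i], n_min = features$eda_n_min[i]
      ),
      thresholds = th,
      window = features$window[i]
    )
    d$calibration <- FALSE
    d
  })
  out <- data.frame(
    window = vapply(decisions, function(d) as.integer(d$window), integer(1)),
    quadrant = vapply(decisions, function(d) d$quadrant, character(1)),
    branch = vapply(decisions, function(d) d$branch %||% NA_character_, character(1)),
    calibration = vapply(decisions, function(d) isTRUE(d$calibration), logical(1)),
    partial = vapply(decisions, function(d) isTRUE(d$partial), logical(1))
  )
  attr(out, "decisions") <- decisions
  attr(out, "streams") <- streams
  class(out) <- c("emotion_decisions", "data.frame")
  out
}

#' Post-calibration quadrant accuracy of a decision table
#'
#' @param decisions An `emotion_decisions` table from [judge_session()].
#' @param labels Ground-truth per-window quadrant labels.
#' @return Fraction of non-calibration windows whose decision equals the
#'   label.
#' @export
judge_accuracy <- function(decisions, labels) {
  keep <- !decisions$calibration
  mean(decisions$quadrant[keep] == labels[decisions$window[keep] + 1L])
}
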