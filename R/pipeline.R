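#' Default run configuration
#'
#' One nested list drives every stage; unknown keys are rejected by
#' [validate_config()] so typos cannot silently fall back to defaults.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(windows_per_segment = 3L, cycles = 1L, fs = 100),
    preprocess = list(
      calibration_mode = "off",
      wavelet = list(levels = 3L, threshold = "universal", mode = "soft"),
      filter = list(cutoff_hz = 10, order = 4L, both = FALSE)
    ),
    features = list(window_length_s = 10),
    selection = list(variance_target = 0.95, weight_threshold = "mean",
                     alpha = 0.10, r_min = 0.3),
    judge = list(calibration_windows = 4L),
    baseline = list(split = 0.7, kernel = "radial", cost = 1),
    adaptation = list(persistence = 1L, refractory = 1L, session_end_after = 2L)
  )
}

.check_keys <- function(cfg, ref, path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad) > 0L) {
    invalid_argument(sprintf("unknown config key(s): %s",
                             paste0(path, bad, collapse = ", ")))
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]])) invalid_argument(sprintf("config key %s%s must be a block", path, nm))
      .check_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Validate and complete a run configuration
#'
#' Fills unset keys from [default_config()]; rejects unknown keys.
#'
#' @param config Partial configuration list (or a path to a JSON file).
#' @return Completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  ref <- default_config()
  .check_keys(config, ref)
  merge_in <- function(cfg, ref) {
    for (nm in names(ref)) {
      if (is.null(cfg[[nm]])) {
        cfg[[nm]] <- ref[[nm]]
      } else if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
        cfg[[nm]] <- merge_in(cfg[[nm]], ref[[nm]])
      }
    }
    cfg
  }
  merge_in(config, ref)
}

#' Semantic hash of a configuration
#'
#' MD5 of the canonical (name-sorted) JSON serialization: the hash
#' changes exactly when a semantic field changes.
#'
#' @param config Configuration list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  canonical <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonical(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline and write its artifacts
#'
#' Simulate -> preprocess -> features -> select -> judge -> adaptation
#' policy -> cross-subject comparison, writing each artifact under
#' `out_dir`. Every run is stamped (`run_info.json`) with the seed and
#' the configuration hash so artifacts are reproducible byte for byte.
#'
#' @param config Configuration list or JSON path (see [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @param compare Also run the cross-subject baseline comparison
#'   (default `TRUE`).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir, compare = TRUE) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  stage <- "simulate"
  paths <- list()
  tryCatch({
    scs <- rep(default_scenarios(cfg$simulate$windows_per_segment, seed = seed),
               cfg$simulate$cycles)
    session <- generate_session(scs, fs = cfg$simulate$fs,
                                window_length_s = cfg$features$window_length_s)
    paths$eda <- write_signal_csv(session$eda, file.path(out_dir, "eda.csv"))
    paths$ppg <- write_signal_csv(session$ppg, file.path(out_dir, "ppg.csv"))
    utils::write.csv(data.frame(window = seq_along(session$labels) - 1L,
                                label = session$labels),
                     file.path(out_dir, "labels.csv"), row.names = FALSE)
    utils::write.csv(data.frame(beat_time_s = session$beat_times),
                     file.path(out_dir, "beats.csv"), row.names = FALSE)

    stage <- "preprocess"
    prep <- preprocess_session(
      session,
      calibration = calibration_params(mode = cfg$preprocess$calibration_mode),
      wavelet_levels = cfg$preprocess$wavelet$levels,
      wavelet_threshold = cfg$preprocess$wavelet$threshold,
      wavelet_mode = cfg$preprocess$wavelet$mode,
      cutoff_hz = cfg$preprocess$filter$cutoff_hz,
      filter_order = cfg$preprocess$filter$order,
      filter_both = cfg$preprocess$filter$both
    )

    stage <- "features"
    feats <- extract_features(prep)
    utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
    paths$features <- file.path(out_dir, "features.csv")

    stage <- "selection"
    sel <- suppressWarnings(select_features(
      feats, session$labels,
      variance_target = cfg$selection$variance_target,
      weight_threshold = cfg$selection$weight_threshold,
      alpha = cfg$selection$alpha, r_min = cfg$selection$r_min
    ))
    paths$selection <- write_selection_report(sel, file.path(out_dir, "selection.json"))

    stage <- "judge"
    dec <- judge_session(prep, calibration_windows = cfg$judge$calibration_windows,
                         features = feats)
    dec_objs <- attr(dec, "decisions")
    jl <- vapply(dec_objs, function(d) {
      jsonlite::toJSON(list(window = d$window, quadrant = d$quadrant,
                            branch = d$branch, calibration = isTRUE(d$calibration),
                            rule_trace = d$rule_trace),
                       auto_unbox = TRUE, digits = NA, null = "null")
    }, character(1))
    writeLines(jl, file.path(out_dir, "decisions.jsonl"))
    paths$decisions <- file.path(out_dir, "decisions.jsonl")

    stage <- "adaptation"
    pol <- policy_step(dec, persistence = cfg$adaptation$persistence,
                       refractory = cfg$adaptation$refractory,
                       session_end_after = cfg$adaptation$session_end_after)
    utils::write.csv(pol$events, file.path(out_dir, "events.csv"), row.names = FALSE)
    paths$events <- file.path(out_dir, "events.csv")
    tab <- tabulate_activations(list(`1` = pol))
    utils::write.csv(tab, file.path(out_dir, "table.csv"), row.names = FALSE, na = "")
    paths$table <- file.path(out_dir, "table.csv")

    if (compare) {
      stage <- "compare"
      cmp <- benchmark_comparison(seed = seed, config = cfg)
      jsonlite::write_json(
        list(
          n_windows = cmp$n_windows,
          quadrants = cmp$quadrants,
          rule_based = cmp$rule_based[c("accuracy", "activations", "correct_activations")],
          baseline = cmp$baseline[c("accuracy", "activations", "correct_activations")]
        ),
        file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA
      )
      paths$comparison <- file.path(out_dir, "comparison.json")
    }

    jsonlite::write_json(
      list(seed = seed, config_hash = config_hash(cfg), config = cfg),
      file.path(out_dir, "run_info.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    paths$run_info <- file.path(out_dir, "run_info.json")
  }, affectstream_error = function(e) {
    stop_affect(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
                "affectstream_pipeline_error")
  })
  invisible(paths)
}

#' Scripted cross-subject comparison benchmark
#'
#' The head-to-head protocol: the SVM baseline is trained on one
#' synthetic subject's labelled session and both approaches are then
#' evaluated on a second subject whose raw channels differ by a positive
#' affine transform (different skin conductance level and pulse
#' amplitude -- the typical between-subject variation). The rule-based
#' approach is invariant to such rescaling by construction; the fixed
#' feature-space baseline is not.
#'
#' @param seed Benchmark seed.
#' @param train_windows_per_class Windows per quadrant in the training
#'   subject's session (default 16).
#' @param eda_gain,eda_offset,ppg_gain Affine inter-subject transform
#'   applied to the evaluation subject's raw traces.
#' @param test_base_ibi_ms Evaluation subject's mean inter-beat interval
#'   (default 950 ms vs the training subject's 800 ms: a slower heart).
#' @param test_jitter_ms Evaluation subject's low/high inter-beat jitter
#'   levels in ms (default `c(25, 110)` vs the training subject's
#'   15/150: individually different heart-rate variability).
#' @param config Optional validated configuration (for judge/baseline/
#'   adaptation parameters).
#' @return A `comparison_result` (see [compare_approaches()]).
#' @export
benchmark_comparison <- function(seed = 1L, train_windows_per_class = 16L,
                                 eda_gain = 3, eda_offset = 5, ppg_gain = 2.5,
                                 test_base_ibi_ms = 950,
                                 test_jitter_ms = c(25, 110),
                                 config = validate_config()) {
  train_session <- generate_session(
    default_scenarios(train_windows_per_class, seed = sub_seed(seed, 401L))
  )
  train_feats <- extract_features(preprocess_session(train_session))
  model <- train_baseline(train_feats, train_session$labels,
                          split = config$baseline$split, seed = seed,
                          kernel = config$baseline$kernel, cost = config$baseline$cost)

  # evaluation subject: two cycles of 2-window segments so every quadrant
  # appears after the calibration prefix (independent draws per cycle),
  # with subject-specific heart rate, HRV jitter, and channel gains
  subject_b <- function(seed0) {
    quads <- c("HANV", "LANV", "LAPV", "HAPV")
    lapply(seq_along(quads), function(i) {
      q <- quads[i]
      quadrant_scenario(
        q, duration_s = 20, seed = sub_seed(seed0, i),
        ibi_jitter_ms = if (q %in% c("LANV", "HAPV")) test_jitter_ms[2] else test_jitter_ms[1],
        base_ibi_ms = test_base_ibi_ms
      )
    })
  }
  test_scen <- c(subject_b(sub_seed(seed, 402L)), subject_b(sub_seed(seed, 403L)))
  test_session <- generate_session(test_scen)
  test_session$eda <- signal_trace(eda_gain * test_session$eda$samples + eda_offset,
                                   fs = test_session$eda$fs, channel = "EDA")
  test_session$ppg <- signal_trace(ppg_gain * test_session$ppg$samples,
                                   fs = test_session$ppg$fs, channel = "PPG")
  compare_approaches(test_session, model,
                     calibration_windows = config$judge$calibration_windows,
                     persistence = config$adaptation$persistence,
                     refractory = config$adaptation$refractory)
}
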