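# Shared fixtures are generated in code and memoized per test run, so the
# slower end-to-end objects (session -> preprocess -> features) are built
# once and reused across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_session <- function(seed = 1L) {
  memo(paste0("session_", seed), generate_session(default_scenarios(3, seed = seed)))
}

default_prepped <- function(seed = 1L) {
  memo(paste0("prep_", seed), preprocess_session(default_session(seed)))
}

default_features <- function(seed = 1L) {
  memo(paste0("features_", seed), extract_features(default_prepped(seed)))
}

# Literal transcription of the decision logic as nested conditionals, kept
# in the tests as the independent oracle for the production rule engine.
oracle_judge <- function(f, th) {
  eda <- NULL
  if (f$eda_range > th$eda_range) {
    if (!(f$n_max > f$n_min)) {
      eda <- "LAPV"
    } else if (f$eda_1dmean > th$eda_1dmean) {
      eda <- "HANV"
    }
  }
  pulse <- NULL
  if (f$ppg_bpnn50 > th$ppg_bpnn50) {
    if (f$ppg_range > th$ppg_range) {
      pulse <- "LANV"
    } else if (f$ppg_1dmean > th$ppg_1dmean) {
      pulse <- "HAPV"
    }
  }
  cand <- c(eda, pulse)
  if (is.null(cand)) return("UNDECIDED")
  for (q in c("HANV", "LANV", "LAPV", "HAPV")) if (q %in% cand) return(q)
  "UNDECIDED"
}

random_feature_tuple <- function() {
  nm <- sample(0:9, 2)
  list(
    eda_range = runif(1), eda_1dmean = runif(1),
    ppg_bpnn50 = runif(1), ppg_range = runif(1), ppg_1dmean = runif(1),
    n_max = nm[1], n_min = nm[2]
  )
}

random_thresholds <- function() {
  list(
    eda_range = runif(1), eda_1dmean = runif(1),
    ppg_bpnn50 = runif(1), ppg_range = runif(1), ppg_1dmean = runif(1)
  )
}
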