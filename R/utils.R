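# Internal helpers: condition constructors and seed hygiene.

stop_affect <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "affectstream_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

invalid_argument <- function(msg, ...) stop_affect(msg, "affectstream_invalid_argument", ...)
format_error     <- function(msg, ...) stop_affect(msg, "affectstream_format_error", ...)

#' @noRd
# Runs `expr` under a fixed RNG seed and restores the caller's RNG state,
# so library code never perturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

# Deterministic sub-seed derivation: one user seed fans out to named
# substreams (eda, ppg, split, ...) without stream overlap in practice.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
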