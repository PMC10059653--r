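#' PCA loading-weight feature subset
#'
#' First stage of the optimal-feature procedure: standardize the feature
#' table, run principal component analysis, retain components up to a
#' cumulative explained-variance target, and score each feature by its
#' loading weight: the absolute loading normalized by the largest
#' absolute loading on that component, maximized over the retained
#' components. The per-component normalization makes the weight measure
#' "how close this feature comes to leading some retained component", so
#' a family of mutually redundant informative features is not penalized
#' for sharing its loading mass. Features whose weight exceeds a
#' threshold (by default the mean weight across features) are kept.
#'
#' Constant columns carry no variance and are excluded with a warning;
#' missing values are imputed by the column mean (`na_policy = "impute"`)
#' or their rows dropped (`"drop"`).
#'
#' @param features Data frame or matrix of per-window feature values
#'   (>= 2 rows, >= 2 usable columns). Non-feature bookkeeping columns
#'   (`window`, `eda_n_min`, `eda_n_max`) are ignored automatically.
#' @param variance_target Cumulative explained-variance fraction for
#'   component retention (default 0.95, high enough to retain the
#'   lower-variance contrast directions that separate quadrants sharing
#'   a dominant feature level).
#' @param weight_threshold `"mean"` (mean absolute-loading weight across
#'   features) or a number in (0, 1).
#' @param na_policy `"impute"` or `"drop"`.
#' @return A partial `selection_report`: list with `loadings`,
#'   `explained_variance`, `n_components`, `weights`, `weight_threshold`,
#'   `subset_pca`, `excluded_constant`.
#' @export
pca_subset <- function(features, variance_target = 0.95,
                       weight_threshold = "mean", na_policy = c("impute", "drop")) {
  na_policy <- match.arg(na_policy)
  X <- as.data.frame(features)
  X <- X[, setdiff(names(X), c("window", "eda_n_min", "eda_n_max")), drop = FALSE]
  if (nrow(X) < 2L || ncol(X) < 2L) {
    invalid_argument("need >= 2 windows and >= 2 features for PCA")
  }
  if (na_policy == "drop") {
    X <- X[stats::complete.cases(X), , drop = FALSE]
  } else {
    for (j in seq_along(X)) {
      nas <- is.na(X[[j]])
      if (any(nas)) X[[j]][nas] <- mean(X[[j]], na.rm = TRUE)
    }
  }
  sds <- vapply(X, stats::sd, numeric(1))
  const <- names(X)[is.na(sds) | sds == 0]
  if (length(const) > 0L) {
    warning(sprintf("excluding %d constant feature column(s): %s",
                    length(const), paste(utils::head(const, 5), collapse = ", ")),
            call. = FALSE)
    X <- X[, setdiff(names(X), const), drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(ev) >= variance_target)[1L]
  if (is.na(ncomp)) ncomp <- length(ev)
  load <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  relload <- sweep(abs(load), 2L, apply(abs(load), 2L, max), "/")
  weights <- apply(relload, 1L, max)
  thr <- if (identical(weight_threshold, "mean")) mean(weights) else as.numeric(weight_threshold)
  structure(
    list(
      loadings = load,
      explained_variance = ev,
      n_components = ncomp,
      weights = weights,
      weight_threshold = thr,
      subset_pca = names(weights)[weights > thr],
      excluded_constant = const
    ),
    class = "selection_report"
  )
}

#' Pearson-correlation significance screen against quadrant labels
#'
#' Second stage of the optimal-feature procedure: each candidate feature
#' is correlated (Pearson, two-sided test) with the one-vs-rest indicator
#' of each emotion-trend quadrant. A feature is kept for a quadrant when
#' `|r| >= r_min` and `P < alpha`; the final optimal subset is the union
#' over quadrants.
#'
#' @param features Feature table (as in [pca_subset()]).
#' @param labels Per-window quadrant labels.
#' @param subset Candidate feature names (typically `subset_pca`);
#'   defaults to all feature columns.
#' @param alpha Significance level (default 0.10; see the methods
#'   vignette for why the screen is liberal and the magnitude floor
#'   `r_min` does the main gating).
#' @param r_min Minimum absolute correlation (default 0.3).
#' @return A `selection_report` with `correlations` (one row per feature
#'   x quadrant: `r`, `p`, `kept`), `subset_final`, and
#'   `correlated_quadrants` (named list).
#' @export
pcc_screen <- function(features, labels, subset = NULL, alpha = 0.10, r_min = 0.3) {
  X <- as.data.frame(features)
  X <- X[, setdiff(names(X), c("window", "eda_n_min", "eda_n_max")), drop = FALSE]
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) {
    invalid_argument("`labels` must have one entry per feature-table row")
  }
  if (is.null(subset)) subset <- names(X)
  subset <- intersect(subset, names(X))
  quads <- intersect(c("HAPV", "HANV", "LANV", "LAPV"), unique(labels))
  missing_q <- setdiff(c("HAPV", "HANV", "LANV", "LAPV"), quads)
  if (length(missing_q) > 0L) {
    warning(sprintf("quadrant(s) absent from labels, skipped: %s",
                    paste(missing_q, collapse = ", ")), call. = FALSE)
  }
  small <- quads[table(factor(labels, levels = quads))[quads] < 3L]
  if (length(small) > 0L) {
    invalid_argument(sprintf("need >= 3 windows per class; too few: %s",
                             paste(small, collapse = ", ")))
  }
  rows <- list()
  for (feat in subset) {
    x <- X[[feat]]
    ok <- is.finite(x)
    for (q in quads) {
      ind <- as.numeric(labels == q)[ok]
      xi <- x[ok]
      if (length(xi) < 3L || stats::sd(xi) == 0 || stats::sd(ind) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(xi, ind, method = "pearson", alternative = "two.sided")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, quadrant = q, r = r, p = p,
        kept = !is.na(r) && abs(r) >= r_min && p < alpha
      )
    }
  }
  cors <- do.call(rbind, rows)
  kept <- cors[cors$kept, , drop = FALSE]
  structure(
    list(
      correlations = cors,
      alpha = alpha, r_min = r_min,
      subset_final = unique(kept$feature),
      correlated_quadrants = split(kept$quadrant, kept$feature)
    ),
    class = "selection_report"
  )
}

#' Run the full optimal-feature-selection procedure
#'
#' PCA loading-weight thresholding followed by the Pearson-correlation
#' significance screen. On sessions generated under the default quadrant
#' signatures the final subset recovers the three optimal features
#' `ppg_bpnn50`, `eda_range` and `eda_1dmean`.
#'
#' @inheritParams pca_subset
#' @inheritParams pcc_screen
#' @return A complete `selection_report` combining both stages:
#'   `subset_final` is a subset of `subset_pca`, which is a subset of the
#'   catalogue.
#' @export
select_features <- function(features, labels, variance_target = 0.95,
                            weight_threshold = "mean", alpha = 0.10, r_min = 0.3,
                            na_policy = "impute") {
  stage1 <- pca_subset(features, variance_target, weight_threshold, na_policy)
  stage2 <- pcc_screen(features, labels, subset = stage1$subset_pca,
                       alpha = alpha, r_min = r_min)
  structure(c(unclass(stage1), unclass(stage2)), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  if (!is.null(x$n_components)) {
    cat(sprintf("  PCA: %d components (%.1f%% variance), weight threshold %.3f -> %d features\n",
                x$n_components, 100 * sum(x$explained_variance[seq_len(x$n_components)]),
                x$weight_threshold, length(x$subset_pca)))
  }
  if (!is.null(x$subset_final)) {
    cat(sprintf("  PCC screen (alpha = %g, |r| >= %g) -> optimal subset (%d): %s\n",
                x$alpha, x$r_min, length(x$subset_final),
                paste(utils::head(x$subset_final, 12), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize / restore a selection report
#'
#' @param report A `selection_report`.
#' @param path JSON file path.
#' @return `read_selection_report()` returns the restored report.
#' @export
write_selection_report <- function(report, path) {
  obj <- unclass(report)
  if (!is.null(obj$loadings)) obj$loadings <- as.data.frame(obj$loadings)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection_report
#' @export
read_selection_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$loadings)) obj$loadings <- as.matrix(obj$loadings)
  if (!is.null(obj$correlated_quadrants)) {
    obj$correlated_quadrants <- lapply(obj$correlated_quadrants, as.character)
  }
  structure(obj, class = "selection_report")
}
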