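test_that("PCA subset keeps the structure-carrying features in a constructed table", {
  set.seed(5)
  n <- 30
  z <- rnorm(n)  # one shared latent factor
  X <- data.frame(
    f1 = z + rnorm(n, sd = 0.05),
    f2 = -2 * z + rnorm(n, sd = 0.05),
    f3 = 0.5 * z + rnorm(n, sd = 0.05)
  )
  for (j in 1:5) X[[paste0("n", j)]] <- rnorm(n)
  X$d1 <- 0
  X$d2 <- 7
  expect_warning(pca_subset(X, variance_target = 0.5), "constant")
  rep <- suppressWarnings(pca_subset(X, variance_target = 0.5))
  # the dominant component is the latent factor; its carriers pass
  expect_true(all(c("f1", "f2", "f3") %in% rep$subset_pca))
  expect_false(all(paste0("n", 1:5) %in% rep$subset_pca))
  expect_setequal(rep$excluded_constant, c("d1", "d2"))
})

test_that("a single dominant direction needs one component at a 0.9 variance target", {
  set.seed(8)
  z <- rnorm(60)
  X <- data.frame(a = z, b = 2 * z + rnorm(60, sd = 0.01), c = -z + rnorm(60, sd = 0.01))
  rep <- pca_subset(X, variance_target = 0.9)
  expect_equal(rep$n_components, 1L)
})

test_that("the PCA subset is invariant to row permutation", {
  ft <- default_features()
  set.seed(2)
  perm <- sample(nrow(ft))
  a <- suppressWarnings(pca_subset(ft))
  b <- suppressWarnings(pca_subset(ft[perm, ]))
  expect_setequal(a$subset_pca, b$subset_pca)
})

test_that("Pearson screening keeps perfect correlates and computes textbook r", {
  labels <- rep(c("HANV", "LANV", "LAPV", "HAPV"), each = 5)
  X <- data.frame(
    ind_hanv = as.numeric(labels == "HANV"),
    other = seq_along(labels)
  )
  rep <- pcc_screen(X, labels)
  expect_true("ind_hanv" %in% rep$subset_final)
  r_row <- subset(rep$correlations, feature == "ind_hanv" & quadrant == "HANV")
  expect_equal(r_row$r, 1)

  # r agrees with the covariance / (sd * sd) formula to 1e-12
  set.seed(31)
  for (rep_i in 1:50) {
    x <- rnorm(30)
    y <- rnorm(30)
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(cor.test(x, y)$estimate), r_hand, tolerance = 1e-12)
  }
})

test_that("a pure-noise feature is screened out under the null", {
  set.seed(77)
  labels <- rep(c("HANV", "LANV", "LAPV", "HAPV"), each = 50)
  excluded <- vapply(1:100, function(i) {
    X <- data.frame(noise = rnorm(200), anchor = as.numeric(labels == "HANV"))
    rep <- pcc_screen(X, labels, subset = "noise", alpha = 0.05)
    !("noise" %in% rep$subset_final)
  }, logical(1))
  expect_gte(mean(excluded), 0.94)
})

test_that("screening warns on absent quadrants and enforces class minimums", {
  labels <- rep(c("HANV", "LANV", "LAPV"), each = 5)
  X <- data.frame(a = rnorm(15), b = rnorm(15))
  expect_warning(pcc_screen(X, labels), "HAPV")
  expect_error(
    suppressWarnings(
      pcc_screen(data.frame(a = rnorm(5)), c("HANV", "HANV", "LANV", "LANV", "LAPV"))
    ),
    class = "affectstream_invalid_argument"
  )
})

test_that("EDA range is selected for both LAPV and HANV on default sessions", {
  s <- default_session()
  rep <- suppressWarnings(select_features(default_features(), s$labels))
  expect_true("eda_range" %in% rep$subset_final)
  expect_setequal(
    intersect(c("LAPV", "HANV"), rep$correlated_quadrants[["eda_range"]]),
    c("LAPV", "HANV")
  )
  # nesting: final subset within PCA subset within the catalogue
  expect_true(all(rep$subset_final %in% rep$subset_pca))
  expect_true(all(rep$subset_pca %in% feature_catalog()$name))
})

test_that("selection reports serialize and restore losslessly", {
  s <- default_session()
  rep <- suppressWarnings(select_features(default_features(), s$labels))
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_report(rep, path)
  back <- read_selection_report(path)
  expect_setequal(back$subset_final, rep$subset_final)
  expect_equal(back$weight_threshold, rep$weight_threshold)
  expect_equal(sort(names(back$correlated_quadrants)), sort(names(rep$correlated_quadrants)))
})
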