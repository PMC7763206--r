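# Polynomial estimator, split, exhaustive search and classification.

test_that("coefficient and combination counts match the model's combinatorics", {
  expect_identical(n_coefficients(17), 171L)
  expect_identical(n_coefficients(1), 3L)
  expect_identical(n_coefficients(7), 36L)
  expect_error(n_coefficients(0), ">= 1")
  expect_identical(n_combinations(32, 7), 3365856)
  expect_identical(n_combinations(32, 1), 32)
  expect_identical(n_combinations(5, 5), 1)
  expect_gt(n_combinations(32, 8), 1e7)  # why the search stops at p = 7
  expect_error(n_combinations(5, 6), "p <= n")
})

test_that("design rows order terms as products (i<=j), linear, constant", {
  expect_equal(build_design_row(2), c(4, 2, 1))
  expect_equal(build_design_row(c(1, 2)), c(1, 2, 4, 1, 2, 1))
  expect_equal(build_design_row(c(0, 0, 0)), c(rep(0, 9), 1))
  expect_length(build_design_row(rnorm(7)), n_coefficients(7))
})

test_that("least squares recovers a known quadratic exactly and handles degeneracy", {
  set.seed(21)
  X <- matrix(rnorm(40), ncol = 2)
  cf_true <- c(0.5, -1, 2, 0.3, -0.7, 1.5)  # (11),(12),(22), b1, b2, gamma
  y <- as.numeric(poly_term_matrix(X) %*% cf_true)
  m <- fit_poly_model(X, y, c("a", "b"))
  expect_lt(max(abs(m$coef - cf_true)), 1e-6)
  expect_lt(model_ssr(m, X, y), 1e-10)
  # constant target: intercept-only solution
  m2 <- fit_poly_model(X, rep(4, 20), c("a", "b"))
  expect_equal(m2$gamma, 4, tolerance = 1e-8)
  expect_lt(max(abs(m2$coef[1:5])), 1e-8)
  expect_error(fit_poly_model(X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("noisy coefficient recovery converges (Monte-Carlo, fixed seed)", {
  set.seed(33)
  X <- matrix(rnorm(1000), ncol = 2)
  cf_true <- c(1, 0.5, -0.5, 2, -1, 3)
  y <- as.numeric(poly_term_matrix(X) %*% cf_true) + rnorm(500, 0, 0.1)
  m <- fit_poly_model(X, y)
  expect_lt(sqrt(mean((m$coef - cf_true)^2)), 0.05)
})

test_that("prediction evaluates the polynomial and validates dimensions", {
  m <- structure(list(features = "x", coef = c(1, 1, 1),
                      alpha = list(`1,1` = 1), beta = c(x = 1), gamma = 1, p = 1L),
                 class = "poly_model")
  expect_equal(predict(m, 2), 7)  # 4 + 2 + 1
  expect_equal(predict(m, 0), 1)  # gamma
  expect_error(predict(m, c(1, 2)), "length")
  set.seed(1)
  X <- matrix(rnorm(30), ncol = 3)
  y <- rnorm(10)
  mf <- fit_poly_model(X, y)
  expect_equal(predict(mf, X), y, tolerance = 1e-6)  # 10 coefs >= 10 points
  expect_equal(model_ssr(mf, X, y), 0, tolerance = 1e-10)
  expect_equal(model_ssr(mf, X, y + c(2, rep(0, 9))), 4, tolerance = 1e-6)
})

test_that("model JSON round-trips through the declared schema", {
  set.seed(6)
  X <- matrix(rnorm(60), ncol = 3)
  m <- fit_poly_model(X, rnorm(20), c("SCL_mar", "HR_mav", "SCR_mav"))
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  j <- jsonlite::read_json(path)
  expect_identical(unlist(j$features), m$features)
  expect_identical(j$p, 3L)
  m2 <- read_model_json(path)
  expect_equal(m2$coef, m$coef, tolerance = 1e-12)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
})

test_that("the stratified split reproduces the printed occurrence table", {
  ratings <- rep(0:10, times = table4_totals)
  sp <- stratified_split(ratings, seed = 1)
  expect_identical(sp$per_level_counts$n_identification,
                   c(35L, 14L, 10L, 8L, 6L, 3L, 3L, 2L, 4L, 2L, 3L))
  expect_identical(sp$per_level_counts$n_validation,
                   c(6L, 2L, 2L, 1L, 1L, 1L, 1L, 0L, 1L, 0L, 0L))
  expect_length(sp$identification_indices, 90L)
  expect_length(sp$validation_indices, 15L)
  expect_identical(sort(c(sp$identification_indices, sp$validation_indices)),
                   seq_along(ratings))
  # per-level membership is preserved
  for (k in 0:10) {
    idx <- which(ratings == k)
    expect_identical(sum(sp$identification_indices %in% idx),
                     sp$per_level_counts$n_identification[k + 1])
  }
  # determinism under seed, variation across seeds possible
  sp2 <- stratified_split(ratings, seed = 1)
  expect_identical(sp$identification_indices, sp2$identification_indices)
  sp3 <- stratified_split(rep(7, 7))
  expect_length(sp3$identification_indices, 6L)
  expect_length(sp3$validation_indices, 1L)
  expect_error(stratified_split(numeric(0)), "empty")
})

test_that("exhaustive search recovers a planted single feature and counts subsets", {
  set.seed(55)
  n <- 60
  X <- matrix(rnorm(n * 8), ncol = 8,
              dimnames = list(NULL, paste0("F", 1:8)))
  y <- 2 * X[, 5]^2 + X[, 5] + 1
  ds <- cbind(data.frame(anx = y), as.data.frame(X))
  sp <- stratified_split(pmin(10, pmax(0, y)), seed = 2)
  sp$identification_indices <- seq_len(n)  # use all rows: recovery check only
  sp$validation_indices <- integer(0)
  res <- exhaustive_search(ds, sp, 1, pool = paste0("F", 1:8))
  expect_identical(res$best_subset, "F5")
  expect_lt(res$ssr_identification, 1e-10)
  expect_identical(res$evaluated_count, 8L)
  res2 <- exhaustive_search(ds, sp, 2, pool = paste0("F", 1:8))
  expect_identical(res2$evaluated_count, 28L)
  expect_error(exhaustive_search(ds, sp, 0), ">= 1")
})

test_that("search agrees with a naive enumerator and S is non-increasing in p", {
  set.seed(77)
  n <- 50
  pool <- paste0("F", 1:6)
  X <- matrix(rnorm(n * 6), ncol = 6, dimnames = list(NULL, pool))
  y <- X[, 2] + 0.5 * X[, 4]^2 + rnorm(n, 0, 0.3)
  ds <- cbind(data.frame(anx = y), as.data.frame(X))
  is_idx <- sort(sample(n, 40))
  sp <- structure(list(identification_indices = is_idx,
                       validation_indices = setdiff(seq_len(n), is_idx)),
                  class = "split_plan")
  prev <- Inf
  for (p in 1:3) {
    mine <- exhaustive_search(ds, sp, p, pool = pool, keep_log = TRUE)
    ref <- naive_search(ds, is_idx, p, pool)
    expect_identical(mine$best_subset, ref$subset)
    expect_equal(mine$ssr_identification, ref$ssr, tolerance = 1e-9)
    expect_equal(mine$log$ssr, ref$all_ssr, tolerance = 1e-9)
    expect_lte(mine$ssr_identification, prev + 1e-12)
    prev <- mine$ssr_identification
  }
})

test_that("threshold classification follows the printed interval conventions", {
  s3 <- class_scheme(3)
  s2 <- class_scheme(2)
  expect_identical(as.character(classify_anxiety(2.91, s3)), "low")
  expect_identical(as.character(classify_anxiety(c(7.12, 7.37), s3)), c("high", "high"))
  expect_identical(as.character(classify_anxiety(3, s3)), "low")     # closed at 3
  expect_identical(as.character(classify_anxiety(7, s3)), "mild")    # closed at 7
  expect_identical(as.character(classify_anxiety(5.0, s2)), "low")   # closed at 5
  expect_identical(as.character(classify_anxiety(-2, s2)), "low")    # interval extension
  expect_identical(as.character(classify_anxiety(12, s3)), "high")
  expect_error(class_scheme(4), "2 or 3")
})

test_that("classification is order-consistent: one class per estimate", {
  set.seed(12)
  est <- runif(500, -3, 13)
  for (s in list(class_scheme(2), class_scheme(3))) {
    cl <- classify_anxiety(est, s)
    expect_false(anyNA(cl))
    # monotone: sorting the estimates sorts the class codes
    expect_true(!is.unsorted(as.integer(cl[order(est)])))
  }
})

test_that("confusion reports normalize rows and compute overall accuracy", {
  s2 <- class_scheme(2)
  perfect <- confusion_report(c("low", "high", "low"), c("low", "high", "low"), s2)
  expect_equal(unclass(perfect$matrix), diag(2), ignore_attr = TRUE)
  expect_equal(perfect$overall_accuracy, 100)
  r <- confusion_report(c("low", "low", "high", "high"),
                        c("low", "high", "high", "high"), s2)
  expect_equal(unname(r$matrix), rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(r$overall_accuracy, 75)
  expect_equal(unname(rowSums(r$matrix)), c(1, 1), tolerance = 1e-12)
  # empty true class flagged, not an error
  r2 <- confusion_report(c("low", "low"), c("low", "high"), s2)
  expect_identical(r2$empty_classes, "high")
  expect_true(all(is.nan(r2$matrix["high", ])))
  expect_error(confusion_report("low", c("low", "high"), s2), "equal length")
})
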