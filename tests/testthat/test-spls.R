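random_problem <- function(n = 20, p = 15, seed = 1) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("F%02d", 1:p))),
       y = rnorm(n))
}

test_that("dense fit reproduces the PLS1 first component exactly", {
  pr <- random_problem(seed = 3)
  fit <- fit_spls1(pr$X, pr$y, keep = ncol(pr$X), scale. = FALSE)
  cv <- drop(crossprod(scale(pr$X, scale = FALSE), pr$y - mean(pr$y)))
  expect_equal(unname(fit$w), unname(cv / sqrt(sum(cv^2))), tolerance = 1e-10)
})

test_that("a noise-free single-feature response is found with keep = 1", {
  pr <- random_problem(n = 30, seed = 4)
  y <- pr$X[, 7]
  fit <- fit_spls1(pr$X, y, keep = 1)
  expect_identical(fit$selected, "F07")
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("sparse selection equals exhaustive top-|covariance| selection", {
  for (s in 1:25) {
    pr <- random_problem(seed = 100 + s)
    keep <- sample(1:14, 1)
    fit <- fit_spls1(pr$X, pr$y, keep, scale. = FALSE)
    cv <- abs(drop(crossprod(scale(pr$X, scale = FALSE), pr$y - mean(pr$y))))
    oracle <- colnames(pr$X)[order(cv, decreasing = TRUE)[1:keep]]
    expect_setequal(fit$selected, oracle)
    # with scaling the oracle is top-|correlation|
    fit_s <- fit_spls1(pr$X, pr$y, keep, scale. = TRUE)
    cr <- abs(cor(pr$X, pr$y))
    expect_setequal(fit_s$selected,
                    colnames(pr$X)[order(cr, decreasing = TRUE)[1:keep]])
  }
})

test_that("flipping the response flips weights but not fit quality", {
  pr <- random_problem(seed = 5)
  f1 <- fit_spls1(pr$X, pr$y, 5)
  f2 <- fit_spls1(pr$X, -pr$y, 5)
  expect_equal(f2$w, -f1$w, tolerance = 1e-10)
  expect_setequal(f2$selected, f1$selected)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-10)
})

test_that("selected sets are nested as keep grows", {
  pr <- random_problem(seed = 6)
  sels <- lapply(c(3, 6, 10, 15), function(k)
    fit_spls1(pr$X, pr$y, k)$selected)
  for (i in 1:3) expect_true(all(sels[[i]] %in% sels[[i + 1]]))
})

test_that("fit validation rejects bad input", {
  pr <- random_problem()
  expect_error(fit_spls1(pr$X, pr$y, 0), "keep")
  expect_error(fit_spls1(pr$X, pr$y, 99), "keep")
  expect_error(fit_spls1(pr$X, rep(1, 20), 3), "zero-variance")
})

test_that("jaccard similarity follows the set definition", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(c("1", "2", "3"), c("2", "3", "4")), 0.5)
  expect_error(jaccard(character(0), character(0)), "empty")
})

test_that("cross-validation is near-perfect on a noise-free problem and null on permuted y", {
  set.seed(20)
  X <- matrix(rnorm(60 * 12), 60, 12, dimnames = list(NULL, sprintf("F%02d", 1:12)))
  y <- 2 * X[, 3]
  cv <- cross_validate(X, y, keep = 1, k = 10, seed = 1)
  expect_gte(cv$cv_r2, 0.99)
  expect_equal(unname(cv$stability["F03"]), 1)

  set.seed(21)
  Xn <- matrix(rnorm(200 * 50), 200, 50, dimnames = list(NULL, sprintf("F%02d", 1:50)))
  yn <- sample(rnorm(200))
  cvn <- cross_validate(Xn, yn, keep = 10, k = 10, seed = 1)
  expect_lt(abs(cvn$cv_r), 0.2)
})

test_that("planted features are more stable than nulls under CV", {
  set.seed(22)
  n <- 120; p <- 80
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("F%03d", 1:p)))
  y <- rowSums(X[, 1:8]) * 0.6 + rnorm(n)
  cv <- cross_validate(X, y, keep = 8, k = 10, seed = 2)
  pv <- wilcox.test(cv$stability[1:8], cv$stability[9:p],
                    alternative = "greater", exact = FALSE)$p.value
  expect_lt(pv, 0.01)
})

test_that("permutation test hits the attainable floor for strong signal and validates input", {
  set.seed(23)
  X <- matrix(rnorm(100 * 30), 100, 30, dimnames = list(NULL, sprintf("F%02d", 1:30)))
  y <- X[, 1] + 0.1 * rnorm(100)
  pt <- permutation_test(X, y, keep = 5, n_perm = 100, seed = 3)
  expect_equal(pt$p_value, 1 / 101)
  expect_error(permutation_test(X, y, keep = 5, n_perm = 0), "n_perm")
})

test_that("keep tuning finds a plausible support size and respects trivial grids", {
  set.seed(24)
  n <- 150; p <- 510
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("F%03d", 1:p)))
  y <- rowSums(X[, 1:10]) * 1.5 + rnorm(n, 0, 0.5)
  tk <- tune_keep(X, y, folds = 10, seed = 4)
  expect_gte(tk$keep, 10)
  expect_lte(tk$keep, 50)
  expect_equal(tune_keep(X, y, grid = 17)$keep, 17)
})

test_that("pure-noise tuning collapses to the smallest candidate most of the time", {
  at_min <- vapply(1:10, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(100 * 200), 100, 200,
                dimnames = list(NULL, sprintf("F%03d", 1:200)))
    y <- rnorm(100)
    tk <- tune_keep(X, y, grid = c(5, 20, 50, 100), folds = 10, seed = s)
    tk$keep == 5
  }, logical(1))
  expect_gte(mean(at_min), 0.8)
})

test_that("self-validation is perfect; independent noise behaves hypergeometrically", {
  set.seed(25)
  X <- matrix(rnorm(80 * 200), 80, 200, dimnames = list(NULL, sprintf("F%03d", 1:200)))
  y <- rowSums(X[, 1:5]) + rnorm(80, 0, 0.5)
  fit <- fit_spls1(X, y, keep = 20)
  self <- external_validate(fit, X, y, folds = 10, seed = 1)
  expect_equal(self$jaccard, 1)
  expect_equal(self$loading_correlation, 1, tolerance = 1e-10)
  expect_equal(self$top_weight_reselected, 1)

  Xe <- matrix(rnorm(80 * 200), 80, 200, dimnames = list(NULL, sprintf("F%03d", 1:200)))
  ye <- rnorm(80)
  ev <- external_validate(fit, Xe, ye, folds = 10, seed = 1)
  # overlap of two effectively random 20-subsets of 200: |A & B| ~ Hypergeom
  max_overlap <- qhyper(0.999, 20, 180, 20)
  expect_lte(ev$jaccard, max_overlap / (40 - max_overlap))
  bad <- Xe[, 1:150]
  expect_error(external_validate(fit, bad, ye), "lacks feature")
})
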