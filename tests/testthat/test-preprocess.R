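test_that("information gain reproduces hand-built contingency cases", {
  # constant feature: one bin, no information
  expect_equal(information_gain(rep(2, 10), rep(c(0, 1), 5)), 0)
  # perfect separation of balanced classes: IG = H(Y) = 1 bit
  expect_equal(information_gain(c(rep(0, 10), rep(1, 10)),
                                c(rep(0, 10), rep(1, 10))), 1.0)
  # {1,2,3,4} vs {0,0,1,1}, 2 equal-frequency bins: 2x2 table, 1 bit
  expect_equal(information_gain(c(1, 2, 3, 4), c(0, 0, 1, 1), bins = 2), 1.0)
  # non-separating: IG bounded by H(Y)
  set.seed(31)
  x <- rnorm(50); y <- rep(c(0, 1), 25)
  ig <- information_gain(x, y)
  expect_gte(ig, 0)
  expect_lte(ig, 1)
  expect_error(information_gain(c(1, 2, 3), c(1, 1, 1)), "both classes")
})

test_that("information gain is invariant to strictly monotone transforms", {
  set.seed(32)
  for (rep in 1:10) {
    x <- sample(rexp(40), 40)  # ties impossible, skewed values
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    base <- information_gain(x, y)
    expect_equal(information_gain(exp(x), y), base)
    expect_equal(information_gain(rank(x), y), base)
    expect_equal(information_gain(x^3 + 5, y), base)
  }
})

test_that("selector retains IG > threshold, with the 80% fallback otherwise", {
  y <- rep(c(0, 1), each = 10)
  sep <- rep(c(0, 1), each = 10)
  m <- cbind(sep = sep, matrix(5, nrow = 20, ncol = 9,
                               dimnames = list(NULL, paste0("const", 1:9))))
  sel <- fit_selector(m, y)
  expect_identical(sel$retained, "sep")
  expect_false(sel$fallback_used)

  # all-constant features: every IG < 0.05, fallback keeps top 80% = 8
  m0 <- matrix(5, nrow = 20, ncol = 10,
               dimnames = list(NULL, paste0("f", 1:10)))
  sel0 <- fit_selector(m0, y)
  expect_true(sel0$fallback_used)
  expect_length(sel0$retained, 8L)

  # retained set identical across row permutations
  set.seed(33)
  mr <- matrix(rnorm(200), nrow = 20,
               dimnames = list(NULL, paste0("f", 1:10)))
  yr <- rbinom(20, 1, 0.5); yr[1:2] <- c(0, 1)
  s1 <- fit_selector(mr, yr)
  perm <- sample(20)
  s2 <- fit_selector(mr[perm, ], yr[perm])
  expect_identical(s1$retained, s2$retained)
  expect_equal(s1$scores, s2$scores)

  expect_error(fit_selector(matrix(numeric(0), 0, 0), integer(0)),
               "non-empty")
})

test_that("min-max scaling follows the fitted bounds without clipping", {
  m <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  sc <- fit_scaler(m)
  tr <- apply_scaler(sc, m)
  expect_equal(unname(tr[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(tr[, "b"]), c(0, 0, 0))   # constant -> 0

  test <- cbind(a = 8, b = 7)
  expect_equal(unname(apply_scaler(sc, test)[, "a"]), 1.5)  # no clipping

  wrong <- cbind(x = 1, b = 2)
  expect_error(apply_scaler(sc, wrong), "do not match")

  # idempotence of fit-then-apply on the fitting data
  expect_equal(apply_scaler(sc, m), apply_scaler(sc, m))
  expect_true(all(tr >= 0 & tr <= 1))
})

test_that("PCA projection is orthonormal, rank-aware and centered", {
  set.seed(34)
  # exact rank-2 data: random combinations of two basis rows
  basis <- matrix(rnorm(2 * 40), 2, 40)
  coef <- matrix(rnorm(30 * 2), 30, 2)
  x <- coef %*% basis
  colnames(x) <- paste0("f", 1:40)
  pr <- fit_projection(x, n_components = 10)
  expect_lte(ncol(pr$rotation), 10L)
  expect_lt(max(pr$sdev[-(1:2)]^2), 1e-8)

  # orthonormal components, non-increasing variance
  gram <- crossprod(pr$rotation)
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  expect_true(all(diff(pr$sdev) <= 1e-12))

  # full-rank data: min(10, features, samples-1) components
  y <- matrix(rnorm(30 * 40), 30, 40, dimnames = list(NULL, paste0("f", 1:40)))
  expect_equal(ncol(fit_projection(y, 10)$rotation), 10L)
  small <- y[1:5, ]
  expect_equal(ncol(fit_projection(small, 10)$rotation), 4L)

  # projecting the mean row gives all-zero scores
  mu <- matrix(colMeans(y), 1, dimnames = list(NULL, colnames(y)))
  expect_lt(max(abs(apply_projection(fit_projection(y, 10), mu))), 1e-10)

  # applying to fitting data reproduces fitted scores; variance bounded
  pr2 <- fit_projection(y, 10)
  sc1 <- apply_projection(pr2, y)
  expect_equal(apply_projection(pr2, y), sc1)
  expect_lte(sum(pr2$sdev^2), sum(apply(y, 2, stats::var)) + 1e-8)

  zz <- y
  colnames(zz) <- paste0("g", 1:40)
  expect_error(apply_projection(pr2, zz), "do not match")
})
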