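test_that("perfectly separated scores yield the maximal report", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  m <- compute_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$auc, 1); expect_equal(m$auprc, 1)
  expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
  expect_equal(m$mcc, 1); expect_equal(m$f1, 1)
})

test_that("threshold metrics reproduce the hand-computed confusion table", {
  # TP=2, FP=1, TN=3, FN=1 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1, 0.05)
  labels <- c(1,   1,   0,   1,   0,   0,   0)
  m <- compute_metrics(scores, labels)
  expect_equal(unname(m$counts), c(2L, 1L, 3L, 1L))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$mcc, 5 / 12, tolerance = 1e-12)
  expect_equal(round(c(m$sensitivity, m$specificity, m$f1, m$mcc), 4),
               c(0.6667, 0.75, 0.6667, 0.4167))
})

test_that("degenerate denominators give 0 and a score at threshold counts positive", {
  # no predicted positives: precision/F1 denominators vanish
  m <- compute_metrics(c(0.1, 0.2, 0.3), c(0, 1, 0))
  expect_equal(m$f1, 0); expect_equal(m$mcc, 0)
  # >= convention at the threshold
  m2 <- suppressWarnings(compute_metrics(c(0.5), c(1)))
  expect_equal(unname(m2$counts["TP"]), 1L)
  # single-class labels: NA ranking metrics, threshold metrics intact
  expect_warning(m3 <- compute_metrics(c(0.9, 0.4), c(1, 1)), "single-class")
  expect_true(is.na(m3$auc) && is.na(m3$auprc))
  expect_equal(m3$sensitivity, 0.5)
})

test_that("rank AUC equals trapezoidal ROC integration", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    m <- suppressWarnings(compute_metrics(scores, labels))
    expect_lt(abs(m$auc - oracle_auc_trapezoid(scores, labels)), 1e-10)
  }
})

test_that("metrics agree with brute-force threshold enumeration on tiny instances", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(c(0, 0.25, 0.5, 0.75, 1), n, replace = TRUE)
    m <- compute_metrics(scores, labels)
    expect_equal(m$auprc, oracle_auprc_enum(scores, labels))
    expect_equal(m$auc, oracle_auc_pairs(scores, labels))
  }
})

test_that("the PR baseline of a random scorer is the positive prevalence", {
  set.seed(43)
  n <- 2000
  labels <- rbinom(n, 1, 0.3)
  scores <- runif(n)
  m <- compute_metrics(scores, labels)
  expect_lt(abs(m$auprc - mean(labels)), 0.05)
  expect_lt(abs(m$auc - 0.5), 0.05)
})

test_that("stratified folds partition the data with balanced classes", {
  labels <- rep(c(0, 1), each = 10)
  f <- make_folds(labels, k = 5, seed = 7)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & labels == 1), 2L)
    expect_equal(sum(f == k & labels == 0), 2L)
  }
  # partition: every sample in exactly one fold
  expect_length(f, 20L)

  # unbalanced sizes still differ by at most one, stratified within one
  labels2 <- c(rep(0, 23), rep(1, 11))
  f2 <- make_folds(labels2, k = 5, seed = 7)
  sizes <- table(f2)
  expect_lte(max(sizes) - min(sizes), 1L)
  pos_per <- table(f2[labels2 == 1])
  expect_lte(max(pos_per) - min(pos_per), 1L)

  expect_identical(make_folds(labels, 5, seed = 3),
                   make_folds(labels, 5, seed = 3))
  expect_false(identical(make_folds(labels, 5, seed = 3),
                         make_folds(labels, 5, seed = 4)))
  expect_error(make_folds(c(1, 1, 1, 1, 0), k = 5), "at least k")
})
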