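test_that("scale function is a decreasing logistic centred at c", {
  p <- metric_params()
  expect_equal(scale_phi(0, p), 0.5)
  expect_equal(scale_phi(-1, p), 1 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(scale_phi(-50, p), 1)
  expect_equal(scale_phi(50, p), 0)
  # logistic symmetry phi(c+d) + phi(c-d) = 1, strict monotonicity
  d <- seq(-3, 3, by = 0.25)
  expect_equal(scale_phi(d, p) + scale_phi(-d, p), rep(1, length(d)),
               tolerance = 1e-12)
  expect_true(all(diff(scale_phi(d, p)) < 0))
  # non-default centre
  p2 <- metric_params(center = -1, shape = 2)
  expect_equal(scale_phi(-1, p2), 0.5)
})

test_that("hit function vanishes at epsilon and peaks at zero deviation", {
  p <- metric_params()
  expect_equal(hit_alpha(0, 1, p), 0)   # |d| == eps
  expect_equal(hit_alpha(0, 1.5, p), 0) # |d| > eps
  expect_equal(hit_alpha(2, 2, p), 1 - exp(-10), tolerance = 1e-12)
  # continuity at the boundary from inside
  expect_lt(hit_alpha(0, 0.999, p), 1e-4)
  # symmetric in the sign of the deviation, bounded
  d <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(hit_alpha(d, 0, p), hit_alpha(-d, 0, p))
  expect_true(all(hit_alpha(d, 0, p) >= 0 &
                  hit_alpha(d, 0, p) <= 1 - exp(-10)))
})

test_that("regression precision and recall follow the weighted formulas", {
  p <- metric_params()
  y <- c(-2.5, -1.2, 0.3, 1.8, -0.4)
  # perfect predictions: alpha constant, weights cancel
  expect_equal(precision_regression(y, y, p), 1 - exp(-10), tolerance = 1e-12)
  expect_equal(recall_regression(y, y, p), 1 - exp(-10), tolerance = 1e-12)
  # every prediction off by more than eps
  expect_equal(precision_regression(y + 2, y, p), 0)
  expect_equal(recall_regression(y + 2, y, p), 0)
  # single-pair worked value: deviation 0.5 -> 1 - exp(-2.5)
  expect_equal(precision_regression(-2, -2.5, p), 1 - exp(-2.5),
               tolerance = 1e-12)
  # manual evaluation of the weighted ratio
  y_hat <- c(-2.0, -1.0, 1.0, 1.5, -0.2)
  a <- hit_alpha(y_hat, y, p)
  expect_equal(precision_regression(y_hat, y, p),
               sum(a * scale_phi(y_hat, p)) / sum(scale_phi(y_hat, p)),
               tolerance = 1e-12)
  expect_equal(recall_regression(y_hat, y, p),
               sum(a * scale_phi(y, p)) / sum(scale_phi(y, p)),
               tolerance = 1e-12)
  # permutation invariance
  o <- c(3, 1, 5, 2, 4)
  expect_equal(precision_regression(y_hat[o], y[o], p),
               precision_regression(y_hat, y, p))
  expect_equal(recall_regression(y_hat[o], y[o], p),
               recall_regression(y_hat, y, p))
  # accurate only where y >> 0 gives near-zero recall
  y2 <- c(5, 6, -2, -3)
  y_hat2 <- c(5, 6, 2, 3) # hits only the strong positives' complements
  expect_lt(recall_regression(y_hat2, y2), 1e-4)
  expect_error(precision_regression(numeric(0), numeric(0)), "non-empty")
})

test_that("rank-based AUC matches an independent implementation", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(3)
  scores <- rnorm(2000)
  labels <- rbinom(2000, 1, 0.5)
  expect_equal(auc(scores, labels), 0.5, tolerance = 0.05)
  # cross-check against pROC on a structured example
  skip_if_not_installed("pROC")
  set.seed(4)
  s <- rnorm(200)
  l <- as.integer(s + rnorm(200) > 0)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(auc(s, l), ref, tolerance = 1e-12)
})

test_that("SRCC equals the rank correlation and rejects degenerate input", {
  a <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(srcc(a, exp(a)), 1)     # monotone transform
  expect_equal(srcc(a, -a), -1)        # reversal
  expect_error(srcc(rep(1, 5), 1:5), "constant")
  # brute-force oracle: Pearson correlation of midranks
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(srcc(x, y), cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("metric report assembles all four scores", {
  set.seed(5)
  y <- rnorm(50)
  y_hat <- y + rnorm(50, sd = 0.3)
  rep <- metric_report(y_hat, y)
  expect_named(rep, c("auc", "srcc", "precision", "recall"))
  expect_true(all(rep >= -1 & rep <= 1))
  expect_equal(rep$srcc, srcc(y_hat, y))
})
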