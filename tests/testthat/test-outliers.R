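test_that("PCA scores are centered, orthogonal, and variance-ordered", {
  withr::with_seed(51, {
    X <- matrix(rnorm(40 * 12), 40, 12)
  })
  pc <- pca_scores(X, 4)
  expect_equal(unname(colMeans(pc$scores)), rep(0, 4), tolerance = 1e-10)
  g <- crossprod(pc$scores)
  offdiag <- g - diag(diag(g))
  expect_lt(max(abs(offdiag)) / max(diag(g)), 1e-8)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)

  # collinear data: one component carries (essentially) all variance
  line <- cbind(1:30, 2 * (1:30) + 5)
  pc1 <- pca_scores(line, 2)
  expect_gt(pc1$variance_explained[1], 1 - 1e-10)
  expect_lt(max(abs(pc1$scores[, 2])), 1e-8)

  expect_error(pca_scores(X, 41), "n_components")
  expect_error(pca_scores(X[1:2, ], 2), "n >= 3")
})

test_that("screening removes a planted outlier first, one at a time", {
  withr::with_seed(52, {
    X <- rbind(matrix(rnorm(100), 50, 2), c(10, 10))
  })
  rep <- screen_outliers(X, alpha = 0.95)
  expect_true(51 %in% rep$removed$index)
  expect_equal(rep$removed$index[1], 51L)      # worst sample goes first
  expect_equal(rep$removed$iteration[1], 1L)
  expect_gt(rep$removed$statistic[1], rep$limit)
  expect_setequal(c(rep$kept, rep$removed$index), 1:51)
  # removal is strictly one per iteration
  expect_equal(rep$removed$iteration, seq_len(nrow(rep$removed)))

  none <- screen_outliers(X, max_removals = 0)
  expect_equal(none$kept, 1:51)
  expect_equal(nrow(none$removed), 0L)
  expect_error(screen_outliers(X, alpha = 1.2), "alpha")
})

test_that("screening never empties the data and warns below the floor", {
  withr::with_seed(53, {
    X <- matrix(rnorm(24), 12, 2)
  })
  # at alpha = 0.5 roughly half the points are "flagged" on every refit,
  # so removal only stops at the 50% floor
  expect_warning(rep <- screen_outliers(X, alpha = 0.5), "floor")
  expect_gte(length(rep$kept), 6)
})

test_that("flagging rate on clean scores matches the chi-square level", {
  withr::with_seed(54, {
    X <- matrix(rnorm(1200 * 2), 1200, 2)
  })
  rep <- screen_outliers(X, alpha = 0.95, max_removals = 0)
  expect_equal(rep$first_pass_flagged / 1200, 0.05, tolerance = 0.4)
})
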