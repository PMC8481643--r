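test_that("PLS1 fits exact low-rank relations", {
  x <- matrix(seq(1, 5, by = 0.5))
  y <- 2 * x[, 1]
  m <- fit_pls(x, y, 1)
  expect_equal(predict(m, x), y, tolerance = 1e-10)

  expect_error(fit_pls(x, y, 9), "n_lv")
  expect_error(fit_pls(x, y, 0), "n_lv")
  expect_error(fit_pls(x, rep(3, nrow(x)), 1), "zero variance")
})

test_that("PLS at full rank equals ordinary least squares", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      n <- sample(8:12, 1); p <- sample(2:6, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- rnorm(n)
      m <- fit_pls(X, y, p)
      ols <- lm.fit(cbind(1, X), y)
      expect_equal(predict(m, X), unname(cbind(1, X) %*% ols$coefficients)[, 1],
                   tolerance = 1e-8)
    }
  })
})

test_that("predict applies stored centering without refitting", {
  withr::with_seed(8, {
    X <- matrix(rnorm(40), 10, 4)
    y <- rnorm(10)
  })
  m <- fit_pls(X, y, 3)
  expect_equal(predict(m, X), as.vector(m$y_mean +
    sweep(X, 2, m$x_mean) %*% m$coefficients))
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean)  # mean row -> y mean
  expect_error(predict(m, X[, 1:3]), "expects 4")
})

test_that("LOOCV selects parsimonious latent-variable counts", {
  withr::with_seed(12, {
    t_lat <- rnorm(30)
    X <- outer(t_lat, rnorm(6)) + 0   # rank-1 design driven by one factor
    y_clean <- 3 * t_lat
  })
  sel <- loocv_select(X, y_clean, 5)
  expect_equal(sel$n_lv, 1L)
  expect_length(sel$rmsecv, 5)
  expect_lt(sel$rmsecv[1], 1e-8)

  withr::with_seed(13, {
    y <- as.vector(X %*% rnorm(6)) + rnorm(30, sd = 0.3)
  })
  sel2 <- loocv_select(X, y, 5)
  # the parsimony rule's own bound
  expect_lte(sel2$rmsecv[sel2$n_lv], 1.02 * min(sel2$rmsecv))
  expect_error(pls_cv_curve(X, y, 40), "max_lv")
})

test_that("k-fold curves are seeded and reproducible", {
  withr::with_seed(14, {
    X <- matrix(rnorm(24 * 5), 24, 5)
    y <- rnorm(24)
  })
  c1 <- pls_cv_curve(X, y, 4, folds = 4, seed = 9)
  c2 <- pls_cv_curve(X, y, 4, folds = 4, seed = 9)
  expect_identical(as.numeric(c1), as.numeric(c2))
  expect_equal(dim(attr(c1, "predictions")), c(24L, 4L))
})
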