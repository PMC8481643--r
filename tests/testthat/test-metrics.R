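test_that("RPD and CV reproduce published arithmetic", {
  expect_equal(round(rpd(75.10, 24.94), 2), 3.01)
  expect_equal(round(rpd(13.86, 4.68), 2), 2.96)
  expect_equal(rpd(5, 5), 1)
  expect_error(rpd(10, 0), "exact fit")

  expect_equal(round(cv_percent(589.24, 98.25), 2), 16.67)
  expect_equal(round(cv_percent(136.50, 13.18), 2), 9.66)
  expect_equal(cv_percent(7, 0), 0)
  expect_error(cv_percent(0, 1), "nonzero")
})

test_that("model ratings follow the adequacy bands, conservatively", {
  expect_equal(as.character(rate_model(0.97, 6.18)), "efficient")
  expect_equal(as.character(rate_model(0.72, 1.94)), "preliminary")
  expect_equal(as.character(rate_model(0.5, 1.0)), "inadequate")
  # mixed tiers fall to the lower one
  expect_equal(as.character(rate_model(0.97, 2.5)), "satisfactory")
  expect_equal(as.character(rate_model(0.75, 5)), "preliminary")
  expect_true(is.ordered(rate_model(0.9, 3)))
  expect_error(rate_model(1.2, 3), "\\[0, 1\\]")
})

test_that("paired t handles regular and degenerate differences", {
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(paired_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  z <- c(0, 0, 0, 0)
  expect_equal(paired_t(z + c(1, -1, 1, -1), z)$t, 0)
  d <- c(1, 2, 3)
  out <- paired_t(d, c(0, 0, 0))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(out$df, 2L)
  expect_equal(out$p_value, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-10)
  # zero-variance, nonzero-mean differences
  inf_case <- paired_t(c(2, 2, 2), c(1, 1, 1))
  expect_equal(inf_case$t, Inf)
  expect_equal(inf_case$p_value, 0)
  expect_error(paired_t(1:2, 1:2), "n >= 3")
})

test_that("evaluate_model reports a complete, self-consistent record", {
  withr::with_seed(31, {
    X <- matrix(rnorm(40 * 5), 40, 5)
    beta <- rnorm(5)
    y <- as.vector(X %*% beta)
  })
  cal <- 1:30; val <- 31:40
  cv <- loocv_select(X[cal, ], y[cal], 5)
  m <- fit_pls(X[cal, ], y[cal], cv$n_lv)
  rep <- evaluate_model(m, X[cal, ], y[cal], X[val, ], y[val], cv = cv)
  # noiseless: perfect prediction, exact-fit flag
  expect_equal(rep$r2c, 1, tolerance = 1e-9)
  expect_equal(rep$r2v, 1, tolerance = 1e-9)
  expect_true(rep$exact_fit)
  expect_equal(rep$rpd_v, Inf)

  withr::with_seed(32, y2 <- y + rnorm(40, sd = 0.5))
  cv2 <- loocv_select(X[cal, ], y2[cal], 5)
  m2 <- fit_pls(X[cal, ], y2[cal], cv2$n_lv)
  r2 <- evaluate_model(m2, X[cal, ], y2[cal], X[val, ], y2[val], cv = cv2)
  # all nine table-style fields populated
  for (f in c("r2c", "rmsec", "sd_cal", "r2cv", "rmsecv", "rpd_cv",
              "r2v", "rmsev", "rpd_v", "sd_val")) {
    expect_true(is.finite(r2[[f]]), info = f)
  }
  # RPD * RMSE recovers SD by construction
  expect_equal(r2$rpd_v * r2$rmsev, r2$sd_val, tolerance = 1e-9)
  expect_equal(r2$rpd_cv * r2$rmsecv, r2$sd_cal, tolerance = 1e-9)
  expect_error(evaluate_model(m2, X[cal, ], y2[cal], X[1:2, ], y2[1:2]),
               "n >= 3")
})
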