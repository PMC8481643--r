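test_that("Kennard-Stone selects the maximin sequence", {
  s <- kennard_stone(matrix(c(0, 1, 4, 10)), n_cal = 3)
  expect_equal(s$order, c(1L, 4L, 3L))          # points 0, 10, 4 in order
  expect_equal(sort(s$validation), 2L)

  s2 <- kennard_stone(matrix(c(0, 1, 4, 10)), n_cal = 2)
  expect_equal(sort(s2$calibration), c(1L, 4L))  # global max-distance pair

  expect_error(kennard_stone(matrix(1:4), n_cal = 1), "n_cal")
  expect_error(kennard_stone(matrix(1:4), n_cal = 4), "n_cal")
})

test_that("floor(3n/4) reproduces the published split sizes", {
  withr::with_seed(3, {
    for (case in list(c(98, 73, 25), c(61, 45, 16), c(37, 27, 10))) {
      X <- matrix(rnorm(case[1] * 3), case[1], 3)
      s <- split_samples(X, "ks")
      expect_length(s$calibration, case[2])
      expect_length(s$validation, case[3])
      expect_setequal(c(s$calibration, s$validation), seq_len(case[1]))
      expect_length(intersect(s$calibration, s$validation), 0)
    }
  })
})

test_that("SPXY combines X and y distances and reduces to KS", {
  # exhaustive 3-point example: combined distance maximal for pair (1, 2)
  s <- spxy(matrix(c(0, 1, 2)), c(0, 10, 1), n_cal = 2)
  expect_equal(sort(s$calibration), c(1L, 2L))

  withr::with_seed(5, {
    X <- matrix(rnorm(12 * 4), 12, 4)
    y <- rnorm(12)
    # constant y: y-term dropped, identical to KS
    expect_equal(spxy(X, rep(1, 12), n_cal = 8)$order,
                 kennard_stone(X, n_cal = 8)$order)
    # y-scale invariance (distances normalized by their maximum)
    expect_equal(spxy(X, 10 * y, n_cal = 8)$order,
                 spxy(X, y, n_cal = 8)$order)
  })
  expect_error(spxy(matrix(1:4), c(1, NA, 2, 3), 2), "finite")
})

test_that("greedy selection matches the brute-force oracle for n <= 8", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      n <- sample(4:8, 1)
      n_cal <- sample(2:min(4, n - 1), 1)
      X <- matrix(rnorm(n * 3), n, 3)
      y <- rnorm(n)
      expect_equal(kennard_stone(X, n_cal)$order, brute_ks(X, n_cal))
      expect_equal(spxy(X, y, n_cal)$order, brute_spxy(X, y, n_cal))
    }
  })
})

test_that("duplicate rows resolve by the tie rule without error", {
  X <- matrix(c(0, 0, 5, 5), 4, 2)   # two identical pairs
  s <- kennard_stone(X, n_cal = 3)
  expect_length(s$calibration, 3)
  expect_equal(s$order[1:2], c(1L, 3L))   # lowest-index maximal pair
})
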