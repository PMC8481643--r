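test_that("MSC inverts affine perturbations and is idempotent", {
  ref <- sin(seq(0, 3, length.out = 80)) + 2
  X <- rbind(ref, 2 * ref + 3, 0.5 * ref - 1)
  out <- msc(X, reference = ref)
  expect_equal(unname(out[1, ]), ref, tolerance = 1e-12)   # self-regression
  expect_equal(unname(attr(out, "msc_a")[1]), 0, tolerance = 1e-10)
  expect_equal(unname(attr(out, "msc_b")[1]), 1, tolerance = 1e-10)
  expect_equal(unname(out[2, ]), ref, tolerance = 1e-12)   # affine inversion
  expect_equal(unname(out[3, ]), ref, tolerance = 1e-12)

  twice <- msc(msc(X, reference = ref), reference = ref)
  expect_equal(unclass(twice), unclass(out), tolerance = 1e-10,
               ignore_attr = TRUE)

  rownames(X) <- c("s1", "flatliner", "s3")
  X[2, ] <- 5   # constant row regresses with slope 0
  expect_error(msc(X, reference = ref), "flatliner")
  expect_error(msc(X[1, , drop = FALSE]), ">= 2 samples")
})

test_that("SNV normalizes rows and is affine-invariant", {
  expect_equal(unname(snv(matrix(c(1, 2, 3), 1))[1, ]), c(-1, 0, 1))
  withr::with_seed(4, {
    for (i in 1:20) {
      x <- matrix(rnorm(60), 1)
      a <- runif(1, -5, 5); b <- runif(1, 0.1, 10)
      expect_equal(snv(b * x + a), snv(x), tolerance = 1e-10)
    }
    X <- matrix(rnorm(200), 5)
    out <- snv(X)
    expect_equal(unname(rowMeans(out)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(out, 1, sd)), rep(1, 5), tolerance = 1e-12)
  })
  Xc <- matrix(7, 2, 10, dimnames = list(c("a", "dead"), NULL))
  expect_error(snv(Xc), "dead")
})

test_that("Savitzky-Golay reproduces and differentiates polynomials", {
  j <- 0:40
  # degree-2 polynomial reproduced exactly at derivative 0, edges included
  poly <- matrix(3 + 0.5 * j - 0.2 * j^2, 1)
  expect_equal(savgol(poly, 7, 2, 0), poly, tolerance = 1e-9)
  # second derivative of j^2 is 2 everywhere
  d2 <- savgol(matrix(j^2, 1), 5, 2, 2)
  expect_equal(unname(d2[1, ]), rep(2, 41), tolerance = 1e-9)
  # first derivative of 3j is 3
  d1 <- savgol(matrix(3 * j, 1), 5, 2, 1)
  expect_equal(unname(d1[1, ]), rep(3, 41), tolerance = 1e-9)

  expect_error(savgol(poly, 6, 2, 1), "odd")
  expect_error(savgol(poly, 3, 3, 1), "exceed")
  expect_error(savgol(poly, 7, 2, 3), "<=")
  expect_error(savgol(matrix(1, 1, 5), 7, 2, 0), "Fewer wavelengths")
})

test_that("SG derivative of order d annihilates polynomials of degree < d", {
  j <- 0:60
  withr::with_seed(9, {
    for (d in 1:2) {
      for (rep in 1:5) {
        coef <- rnorm(d)   # random polynomial of degree d-1
        row <- matrix(colSums(coef * t(outer(j, 0:(d - 1), "^"))), 1)
        out <- savgol(row, 11, 3, d)
        expect_lt(max(abs(out)), 1e-9)
      }
    }
  })
})

test_that("Norris gap-segment derivative matches a linear ramp slope", {
  j <- 0:99
  d1 <- norris_gap(matrix(2.5 * j, 1), segment = 5, gap = 4, derivative = 1)
  expect_equal(unname(d1[1, 20:80]), rep(2.5, 61), tolerance = 1e-9)
  expect_error(norris_gap(matrix(j, 1), segment = 4), "odd")
})

test_that("recipes parse, validate, and compose with state reuse", {
  r <- parse_recipe("MSC+SG51p2d2")
  expect_equal(format(r), "MSC+SG51p2d2")
  expect_equal(r$window, 51L)
  expect_error(parse_recipe("EMSC+SG51p2d2"), "Cannot parse")
  expect_error(preprocess_recipe("msc", 52, 2, 2), "odd")
  expect_error(preprocess_recipe("msc", 51, 1, 2), "derivative|<=")

  withr::with_seed(2, {
    Xc <- matrix(rnorm(10 * 80, mean = 5), 10, 80)
    Xv <- matrix(rnorm(4 * 80, mean = 5), 4, 80)
  })
  rec <- preprocess_recipe("msc", 11, 2, 2)
  cal <- apply_recipe(Xc, rec)
  val <- apply_recipe(Xv, rec, state = cal$state)
  # validation corrected against the calibration mean spectrum
  manual <- savgol(msc(Xv, reference = colMeans(Xc)), 11, 2, 2)
  expect_equal(val$treated, manual, ignore_attr = TRUE)
  expect_equal(cal$state$msc_reference, colMeans(Xc))

  # chained manual calls equal apply_recipe exactly
  manual_cal <- savgol(msc(Xc), 11, 2, 2)
  expect_equal(cal$treated, manual_cal, ignore_attr = TRUE)

  # 'none' recipe is pure smoothing
  sm <- apply_recipe(Xc, preprocess_recipe("none", 11, 2, 0))
  expect_equal(sm$treated, savgol(Xc, 11, 2, 0), ignore_attr = TRUE)
  expect_null(sm$state$msc_reference)
})
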