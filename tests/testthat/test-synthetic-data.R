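test_that("concentration draws respect bounds, seeds, and degenerate sd", {
  st <- analyte_stats("hulled_flour")
  d1 <- draw_concentrations(50, st, seed = 5)
  d2 <- draw_concentrations(50, st, seed = 5)
  expect_identical(d1, d2)
  vals <- as.matrix(tibble::as_tibble(d1)[, sorghum_analytes])
  expect_true(all(sweep(vals, 2, st$min, ">=")))
  expect_true(all(sweep(vals, 2, st$max, "<=")))

  st0 <- st; st0$sd <- 0
  d0 <- draw_concentrations(10, st0, seed = 1)
  expect_equal(unique(d0$starch), st$mean[st$analyte == "starch"])

  bad <- st; bad$min[1] <- bad$max[1] + 1
  expect_error(draw_concentrations(5, bad, seed = 1), "Infeasible")
  expect_error(draw_concentrations(0, st, seed = 1), ">= 1")
})

test_that("sample moments converge to the truncated-normal oracle", {
  # starch with published whole-grain statistics; truncation at +1.99 sd
  # shifts the mean by ~ -5 g/kg, which the analytic oracle predicts
  st <- analyte_stats("whole_grain")
  big <- draw_concentrations(10000, st, seed = 99)
  starch <- big$starch
  expect_lt(abs(mean(starch) - 589.24) / 589.24, 0.02)  # within 2% of target
  oracle <- truncnorm_moments(589.24, 98.25, 298.67, 784.79)
  se_mean <- oracle$sd / sqrt(10000)
  expect_lt(abs(mean(starch) - oracle$mean), 3 * se_mean)
  se_sd <- oracle$sd / sqrt(2 * 10000)
  expect_lt(abs(sd(starch) - oracle$sd), 3 * se_sd)
})

test_that("correlated draws honour the requested correlation sign", {
  st <- analyte_stats("hulled_flour")
  R <- diag(8); R[1, 2] <- R[2, 1] <- 0.8   # starch-protein
  d <- draw_concentrations(3000, st, correlation = R, seed = 3)
  expect_gt(cor(d$starch, d$protein), 0.6)
  bad <- diag(8); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(draw_concentrations(5, st, correlation = bad), "semidefinite")
})

test_that("the open-mixture renderer is linear and homogeneous", {
  st <- analyte_stats("hulled_flour")
  conc <- draw_concentrations(3, st, seed = 2)
  wn <- default_grid(120)
  zero_fx <- effect_model(0, 0, 0, 0)
  zero <- conc
  for (a in sorghum_analytes) zero[[a]] <- 0
  x0 <- render_spectra(zero, effects = zero_fx, wn = wn, background = NULL)
  expect_equal(max(abs(spectra_matrix(x0))), 0)

  x1 <- render_spectra(conc, effects = zero_fx, wn = wn, background = NULL)
  doubled <- conc
  for (a in sorghum_analytes) doubled[[a]] <- 2 * conc[[a]]
  x2 <- render_spectra(doubled, effects = zero_fx, wn = wn, background = NULL)
  expect_equal(spectra_matrix(x2), 2 * spectra_matrix(x1), tolerance = 1e-12)

  # fixed b = 2, a = 0.1: exactly an affine map of the clean mixture
  xf <- render_spectra(conc, effects = zero_fx, wn = wn, background = NULL,
                       fixed_effects = list(b = 2, a = 0.1))
  expect_equal(spectra_matrix(xf), 2 * spectra_matrix(x1) + 0.1,
               tolerance = 1e-12)
})

test_that("MSC restores scatter-affected replicates of one mixture", {
  st <- analyte_stats("hull_less_flour")
  one <- draw_concentrations(1, st, seed = 4)
  reps <- one[rep(1, 12), ]
  reps$sample_id <- sprintf("R%02d", 1:12)
  reps <- as_ref_chemistry(reps)
  wn <- default_grid(150)
  clean <- spectra_matrix(render_spectra(reps, effects = effect_model(0, 0, 0, 0),
                                         wn = wn, background = NULL))
  scattered <- render_spectra(reps, effects = effect_model(0.2, 0.05, 0, 0),
                              wn = wn, background = NULL, seed = 8)
  fixed <- msc(spectra_matrix(scattered), reference = clean[1, ])
  expect_lt(max(abs(sweep(unclass(fixed), 2, clean[1, ]))), 1e-8)
})

test_that("a noiseless, scatter-free study is exactly low-rank", {
  study <- simulate_study(study_config(
    n_hulled = 25L, n_hull_less = 15L, wn = default_grid(200),
    effects = effect_model(0, 0, 0, 0), seed = 31
  ))
  ds <- study_dataset(study, "whole_grain_flour")
  X <- spectra_matrix(ds$spectra)
  y <- ds$chemistry$protein
  s <- kennard_stone(X)
  m <- fit_pls(X[s$calibration, ], y[s$calibration], 8)   # one LV per analyte
  pred <- predict(m, X[s$validation, ])
  expect_lt(1 - cor(pred, y[s$validation])^2, 1e-10)
})

test_that("simulate_study emulates the panel layout reproducibly", {
  study <- simulate_study(study_config(seed = 7))
  expect_equal(nrow(study$chemistry), 98L)
  expect_length(wavenumbers(study$spectra$whole_grain), 1557L)
  expect_equal(nrow(study$spectra$hulled_flour), 61L)
  expect_equal(nrow(study$spectra$hull_less_flour), 37L)
  expect_false(anyNA(study$chemistry$grade))   # every sample exactly one label

  again <- simulate_study(study_config(seed = 7))
  expect_identical(study$chemistry, again$chemistry)
  expect_equal(spectra_matrix(study$spectra$whole_grain),
               spectra_matrix(again$spectra$whole_grain))
  # byte-identical CSV output under a fixed seed
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(study$spectra$hull_less_flour, f1)
  write_spectra(again$spectra$hull_less_flour, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulate_study(study_config(n_hulled = 4L, n_hull_less = 3L)),
               "n >= 8")
})
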