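test_that("spectra CSV round trip is lossless and sorts wavenumbers", {
  sp <- toy_spectra()
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, f)
  back <- read_spectra(f)
  expect_s3_class(back, "nir_spectra")
  expect_equal(spectra_matrix(back), spectra_matrix(sp), tolerance = 1e-12)
  expect_equal(wavenumbers(back), wavenumbers(sp), tolerance = 1e-12)

  # descending columns on disk come back ascending
  m <- matrix(1:6, 2, 3)
  desc <- data.frame(sample_id = c("a", "b"),
                     `9000` = m[, 1], `5000` = m[, 2], `4000` = m[, 3],
                     check.names = FALSE)
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(desc, f2)
  sp2 <- read_spectra(f2)
  expect_equal(wavenumbers(sp2), c(4000, 5000, 9000))
  expect_equal(unname(spectra_matrix(sp2)[, 3]), m[, 1])
})

test_that("spectra validation catches malformed input", {
  wn <- seq(4000, 10000, length.out = 4)
  expect_error(nir_spectra(matrix(1, 2, 4), wn, c("a", "a")), "Duplicate")
  expect_error(nir_spectra(matrix(c(1, NA, 1, 1, 1, 1, 1, 1), 2, 4),
                           wn, c("a", "b")), "non-finite|Missing")
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(sample_id = "a", notanumber = 1), f)
  expect_error(read_spectra(f), "Non-numeric wavenumber")
  expect_error(read_spectra(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("reference chemistry reads with extra metadata and validates", {
  chem <- tibble::tibble(sample_id = c("S1", "S2"),
    starch = c(589.24, 500), protein = c(136, 130), fat = c(36, 40),
    tannin = c(13, 15), cellulose = c(116, 120), hemicellulose = c(56, 60),
    lignin = c(57, 50), ash = c(23, 25), site = c("A", "B"))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(chem, f)
  ref <- read_reference(f)
  expect_s3_class(ref, "ref_chemistry")
  expect_equal(ref$starch[ref$sample_id == "S1"], 589.24)
  expect_true("site" %in% names(ref))   # unknown column kept as metadata

  expect_error(as_ref_chemistry(chem[0, ]), "no rows")
  expect_error(as_ref_chemistry(dplyr::select(chem, -"tannin")), "tannin")
  bad <- chem; bad$fat[1] <- -1
  expect_error(as_ref_chemistry(bad), ">= 0")
})

test_that("align_dataset inner-joins on sample_id, order-invariantly", {
  sp <- toy_spectra()
  chem <- tibble::tibble(sample_id = sp$sample_id)
  for (a in sorghum_analytes) chem[[a]] <- seq_len(nrow(sp)) + 10
  al <- align_dataset(sp, as_ref_chemistry(chem))
  expect_identical(al$spectra$sample_id, al$chemistry$sample_id)
  expect_equal(nrow(al$spectra), 4L)

  shuffled <- as_ref_chemistry(chem[c(3, 1, 4, 2), ])
  al2 <- align_dataset(sp, shuffled)
  expect_equal(al2$chemistry, al$chemistry)

  expect_warning(al3 <- align_dataset(sp, as_ref_chemistry(chem[-2, ])),
                 "Dropping 1")
  expect_equal(nrow(al3$spectra), 3L)
  expect_true(sp$sample_id[2] %in% al3$dropped)

  other <- chem; other$sample_id <- paste0("X", other$sample_id)
  expect_error(align_dataset(sp, as_ref_chemistry(other)), "No shared")

  # idempotence
  al4 <- align_dataset(al$spectra, al$chemistry)
  expect_equal(al4$chemistry, al$chemistry)
  expect_equal(spectra_matrix(al4$spectra), spectra_matrix(al$spectra))
})
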