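# Seeded synthetic FT-NIR study generator. Spectra are Beer-Lambert linear
# mixtures of per-analyte Gaussian band spectra, wrapped in the effects the
# pretreatments are designed to remove: multiplicative scatter, additive
# offset, linear baseline tilt, and i.i.d. instrument noise. Whole grains
# scatter about twice as strongly as milled flours (hull/particle-size
# scattering), which is what motivates MSC/SNV in the first place.

#' Default instrument wavenumber grid
#'
#' 1,557 evenly spaced points spanning 4,000-10,000 cm^-1 inclusive,
#' matching the variable count of the emulated instrument configuration
#' (step ~3.856 cm^-1).
#'
#' @param n Number of grid points.
#' @param range Wavenumber range in cm^-1.
#' @return Ascending numeric vector.
#' @export
default_grid <- function(n = 1557L, range = c(4000, 10000)) {
  seq(range[1], range[2], length.out = n)
}

#' Per-analyte concentration statistics for the generator
#'
#' Mean, SD, minimum and maximum (g kg^-1) per analyte, defaulting to the
#' published calibration-subset descriptive statistics of the chosen sample
#' format (see [sorghum_reference_stats()]).
#'
#' @param format One of [sorghum_formats].
#' @return Tibble with columns `analyte`, `mean`, `sd`, `min`, `max`.
#' @export
analyte_stats <- function(format = "hulled_flour") {
  format <- match.arg(format, sorghum_formats)
  st <- dplyr::filter(sorghum_reference_stats(),
                      .data$format == !!format, .data$subset == "C")
  dplyr::select(st, "analyte", "mean", "sd", "min", "max")
}

#' Analytic moments of a truncated normal distribution
#'
#' Closed-form mean and SD of `N(mean, sd^2)` truncated to `[min, max]`;
#' the independent oracle for the concentration sampler. With bounds a few
#' SDs out, truncation shifts the mean and shrinks the SD noticeably, so
#' convergence tests compare against these moments, not the raw inputs.
#'
#' @param mean,sd,min,max Parent-normal parameters and truncation bounds
#'   (vectorized).
#' @return Tibble with columns `mean`, `sd` of the truncated distribution.
#' @export
truncnorm_moments <- function(mean, sd, min, max) {
  a <- (min - mean) / sd
  b <- (max - mean) / sd
  z <- pnorm(b) - pnorm(a)
  shift <- (dnorm(a) - dnorm(b)) / z
  mu <- mean + sd * shift
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z - shift^2)
  tibble::tibble(mean = mu, sd = sqrt(v))
}

#' Draw analyte concentrations
#'
#' Truncated-normal sampling by rejection: per analyte from
#' `N(mean, sd^2)` truncated to `[min, max]`, or from a truncated
#' multivariate normal when a correlation matrix is supplied. `sd = 0`
#' degenerates to the mean.
#'
#' @param n Number of samples, `>= 1`.
#' @param stats An [analyte_stats()]-shaped tibble.
#' @param correlation Optional positive-semidefinite analyte correlation
#'   matrix (default identity).
#' @param seed Integer seed; fixes the output exactly.
#' @return A `ref_chemistry` tibble with generated `sample_id`s.
#' @export
draw_concentrations <- function(n, stats, correlation = NULL, seed = 1L) {
  if (n < 1L) abort("`n` must be >= 1.")
  if (any(stats$min > stats$max)) abort("Infeasible truncation: min > max.")
  if (any(stats$sd < 0)) abort("`sd` must be >= 0.")
  k <- nrow(stats)
  L <- NULL
  if (!is.null(correlation)) {
    if (!isTRUE(all.equal(dim(correlation), c(k, k)))) {
      abort("`correlation` must be an analyte x analyte matrix.")
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) abort("`correlation` must be positive semidefinite.")
    L <- t(chol(correlation + diag(1e-10, k)))
  }
  draw_block <- function(m) {
    z <- matrix(rnorm(m * k), m, k)
    if (!is.null(L)) z <- z %*% t(L)
    sweep(sweep(z, 2, stats$sd, "*"), 2, stats$mean, "+")
  }
  withr::with_seed(seed, {
    out <- draw_block(n)
    for (rep in seq_len(10000L)) {
      bad <- which(
        rowSums(sweep(out, 2, stats$min, "<") |
                  sweep(out, 2, stats$max, ">")) > 0
      )
      if (length(bad) == 0L) break
      out[bad, ] <- draw_block(length(bad))
    }
    if (length(bad <- which(rowSums(
      sweep(out, 2, stats$min, "<") | sweep(out, 2, stats$max, ">")) > 0))) {
      abort("Rejection sampling failed to satisfy the truncation bounds.")
    }
    colnames(out) <- stats$analyte
    df <- tibble::as_tibble(out)
    df <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%03d", seq_len(n))), df
    )
    as_ref_chemistry(df)
  })
}

.band <- function(center, width, height) {
  tibble::tibble(center = center, width = width, height = height)
}

#' Default pure-component band library
#'
#' For each analyte, a non-negative absorptivity spectrum built as a sum of
#' Gaussian bands (center cm^-1, width cm^-1, height in absorbance per
#' g kg^-1). Centers sit at conventional near-infrared assignments
#' (C-H / O-H / N-H overtone and combination bands, all with at least one
#' band below 9,000 cm^-1 where grain absorption peaks); heights are scaled
#' so a mean mixture spans roughly 0.25-0.43 absorbance. Ash carries weak
#' broad stand-in bands (minerals have no true NIR absorbance); values are
#' documented defaults, not spectroscopic claims.
#'
#' @return Named list of band tibbles, one per analyte.
#' @export
default_band_library <- function() {
  list(
    starch = .band(c(4760, 5200, 6900, 8300),
                   c(150, 220, 280, 260),
                   c(4.0e-4, 3.5e-4, 2.5e-4, 1.0e-4)),
    protein = .band(c(4600, 5000, 6650, 8600),
                    c(110, 180, 240, 220),
                    c(8.0e-4, 5.0e-4, 4.0e-4, 1.5e-4)),
    fat = .band(c(4330, 5680, 5800, 8260),
                c(90, 110, 120, 160),
                c(1.5e-3, 1.2e-3, 1.4e-3, 5.0e-4)),
    tannin = .band(c(4680, 6000, 7000),
                   c(120, 200, 260),
                   c(3.0e-3, 2.0e-3, 2.5e-3)),
    cellulose = .band(c(4280, 4890, 6300, 7180),
                      c(100, 160, 240, 200),
                      c(6.0e-4, 5.0e-4, 4.0e-4, 3.0e-4)),
    hemicellulose = .band(c(4400, 5220, 6720, 8270),
                          c(110, 170, 230, 210),
                          c(9.0e-4, 7.0e-4, 5.0e-4, 2.0e-4)),
    lignin = .band(c(4546, 5980, 6880),
                   c(100, 180, 250),
                   c(9.0e-4, 8.0e-4, 5.0e-4)),
    ash = .band(c(4150, 5450, 7600),
                c(150, 250, 300),
                c(1.2e-3, 9.0e-4, 4.0e-4))
  )
}

#' Matrix (background) component of the grain mixture
#'
#' A grain is a closed mixture: the eight assayed constituents plus the
#' residual matrix (moisture, soluble sugars, pentosans not captured by the
#' assays) sum to a constant total mass. The renderer therefore adds a
#' background component at concentration `total_mass - sum(analytes)` with
#' its own broad absorptivity spectrum (water combination/overtone bands
#' around 5,150 and 6,900 cm^-1). Without this closure the generator would
#' emulate an impossible material whose total mass varies freely, and
#' scatter correction would delete genuine composition information. The
#' default `total_mass` of 1,600 g kg^-1 sits safely above the largest
#' achievable assay sum (the overlapping wet-chemistry assays double-count
#' some mass, so sums exceed 1,000 g kg^-1).
#'
#' @param total_mass Closed-mixture total in g kg^-1.
#' @param bands Band tibble (center, width, height) of the matrix spectrum.
#' @return A `background_model` list.
#' @export
background_model <- function(total_mass = 1600,
                             bands = .band(c(4600, 5150, 6900, 8500),
                                           c(400, 300, 350, 500),
                                           c(5.0e-4, 1.0e-3, 8.0e-4, 2.0e-4))) {
  structure(list(total_mass = total_mass, bands = bands),
            class = "background_model")
}

#' Evaluate a band library on a wavenumber grid
#'
#' @param library A band library (see [default_band_library()]).
#' @param wn Wavenumber grid.
#' @return Matrix (wavelengths x analytes) of absorptivities per g kg^-1.
#' @export
band_matrix <- function(library = default_band_library(),
                        wn = default_grid()) {
  vapply(library, function(bands) {
    rowSums(vapply(seq_len(nrow(bands)), function(b) {
      bands$height[b] * exp(-0.5 * ((wn - bands$center[b]) / bands$width[b])^2)
    }, numeric(length(wn))))
  }, numeric(length(wn)))
}

#' Measurement effect model
#'
#' Distributions for the per-sample multiplicative scatter factor
#' `b ~ exp(N(0, scatter_sd^2))` (mean ~1, always positive), additive
#' offset `a ~ N(0, offset_sd^2)`, linear baseline tilt coefficient
#' `t ~ N(0, tilt_sd^2)` and i.i.d. instrument noise (absorbance units).
#' Whole grains get `whole_grain_multiplier` times the scatter/offset/tilt
#' spread of flours.
#'
#' @param scatter_sd Log-scale SD of the multiplicative factor (flours).
#' @param offset_sd SD of the additive offset, AU.
#' @param tilt_sd SD of the baseline tilt, AU over the full range.
#' @param noise_sd SD of the i.i.d. noise, AU, `>= 0`.
#' @param whole_grain_multiplier Spread multiplier for whole grains.
#' @return An `effect_model` list.
#' @export
effect_model <- function(scatter_sd = 0.08, offset_sd = 0.01,
                         tilt_sd = 0.01, noise_sd = 2e-4,
                         whole_grain_multiplier = 2) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (scatter_sd < 0 || offset_sd < 0 || tilt_sd < 0) {
    abort("Effect spreads must be >= 0.")
  }
  structure(
    list(scatter_sd = scatter_sd, offset_sd = offset_sd, tilt_sd = tilt_sd,
         noise_sd = noise_sd, whole_grain_multiplier = whole_grain_multiplier),
    class = "effect_model"
  )
}

#' Render spectra from concentrations
#'
#' Forward model per sample i:
#' `x_i = b_i * (sum_a c_ia * s_a) + a_i + t_i * (nu - mean(nu)) / range(nu)
#'  + eps_i`,
#' with `(a_i, b_i, t_i)` drawn from the effect model (spreads multiplied
#' by the format factor for whole grains) and `eps_i` i.i.d. noise. When a
#' [background_model()] is supplied (the default), the sum over components
#' additionally includes the residual matrix at concentration
#' `total_mass - sum(analytes)`, closing the mixture; pass
#' `background = NULL` for the bare open-mixture renderer (exactly linear
#' and homogeneous in the analyte concentrations).
#'
#' @param conc A `ref_chemistry` tibble.
#' @param library Band library.
#' @param effects An [effect_model()].
#' @param seed Integer seed.
#' @param wn Wavenumber grid.
#' @param format Presentation format tag for all rendered samples.
#' @param background A [background_model()], or `NULL` for none.
#' @param fixed_effects Optional list with any of `b`, `a`, `t` (scalars or
#'   per-sample vectors) overriding the random effect draws — useful to
#'   verify the affine construction exactly.
#' @return A `nir_spectra` tibble.
#' @export
render_spectra <- function(conc, library = default_band_library(),
                           effects = effect_model(), seed = 1L,
                           wn = default_grid(), format = "whole_grain_flour",
                           background = background_model(),
                           fixed_effects = NULL) {
  if (nrow(conc) == 0L) abort("`conc` must be non-empty.")
  S <- band_matrix(library, wn)
  if (!identical(colnames(S), sorghum_analytes)) {
    S <- S[, sorghum_analytes, drop = FALSE]
  }
  C <- as.matrix(tibble::as_tibble(conc)[, sorghum_analytes])
  n <- nrow(C); p <- length(wn)
  clean <- C %*% t(S)
  if (!is.null(background)) {
    bg_conc <- background$total_mass - rowSums(C)
    if (any(bg_conc < 0)) {
      abort("Analyte sums exceed `total_mass`; raise background_model(total_mass=).")
    }
    s_bg <- band_matrix(list(background = background$bands), wn)[, 1]
    clean <- clean + tcrossprod(bg_conc, s_bg)
  }
  mult <- if (format == "whole_grain") effects$whole_grain_multiplier else 1
  ramp <- (wn - mean(wn)) / (max(wn) - min(wn))
  withr::with_seed(seed, {
    b <- exp(rnorm(n, 0, effects$scatter_sd * mult))
    a <- rnorm(n, 0, effects$offset_sd * mult)
    tl <- rnorm(n, 0, effects$tilt_sd * mult)
    eps <- matrix(rnorm(n * p, 0, effects$noise_sd), n, p)
    if (!is.null(fixed_effects)) {
      if (!is.null(fixed_effects$b)) b <- rep_len(fixed_effects$b, n)
      if (!is.null(fixed_effects$a)) a <- rep_len(fixed_effects$a, n)
      if (!is.null(fixed_effects$t)) tl <- rep_len(fixed_effects$t, n)
    }
    x <- b * clean + a + tcrossprod(tl, ramp) + eps
    nir_spectra(x, wn, conc$sample_id, format = format)
  })
}

#' Study simulation settings
#'
#' Defaults state the emulated world: 98 grains (61 hulled + 37 hull-less),
#' concentrations from the published per-morphology calibration statistics,
#' 1,557-point grid over 4,000-10,000 cm^-1, and the default effect model.
#'
#' @param n_hulled,n_hull_less Samples per grain morphology.
#' @param effects An [effect_model()].
#' @param library Band library.
#' @param wn Wavenumber grid.
#' @param correlation Optional analyte correlation matrix.
#' @param background A [background_model()] closing the mixture, or `NULL`.
#' @param rules [grading_rules()] used to label samples.
#' @param seed Integer seed.
#' @return A `study_config` list.
#' @export
study_config <- function(n_hulled = 61L, n_hull_less = 37L,
                         effects = effect_model(),
                         library = default_band_library(),
                         wn = default_grid(), correlation = NULL,
                         background = background_model(),
                         rules = grading_rules(), seed = 42L) {
  structure(
    list(n_hulled = as.integer(n_hulled),
         n_hull_less = as.integer(n_hull_less),
         effects = effects, library = library, wn = wn,
         correlation = correlation, background = background,
         rules = rules, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Simulate a complete grading study
#'
#' Draws one chemistry table for the panel (hulled and hull-less grains
#' from their respective published calibration statistics), grades every
#' sample, and renders the four spectra sets: the full panel as whole
#' grains (stronger scatter) and as whole grain flours, plus the hulled and
#' hull-less flour subsets. Chemistry is identical across formats, as in a
#' real study where the same grains are scanned before and after milling.
#'
#' @param config A [study_config()].
#' @return A `sorghum_study`: list with `chemistry` (`ref_chemistry` with
#'   `morphology` and `grade` columns), `spectra` (named list of
#'   `nir_spectra`, one per format) and `config`.
#' @export
#' @examples
#' \donttest{
#' study <- simulate_study(study_config(seed = 7))
#' study$chemistry
#' }
simulate_study <- function(config = study_config()) {
  n <- config$n_hulled + config$n_hull_less
  if (n < 8L) abort("Need n >= 8 to partition 3:1 with >= 2 validation samples.")
  seed <- config$seed
  hulled <- draw_concentrations(config$n_hulled, analyte_stats("hulled_flour"),
                                correlation = config$correlation,
                                seed = seed)
  hull_less <- draw_concentrations(config$n_hull_less,
                                   analyte_stats("hull_less_flour"),
                                   correlation = config$correlation,
                                   seed = seed + 1L)
  chem <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(hulled), morphology = "hulled"),
    dplyr::mutate(tibble::as_tibble(hull_less), morphology = "hull_less")
  )
  chem$sample_id <- sprintf("S%03d", seq_len(n))
  chem$grade <- grade_sample(chem$tannin, chem$hemicellulose, chem$starch,
                             rules = config$rules)
  chem <- as_ref_chemistry(chem)
  subset_chem <- function(morph) chem[chem$morphology == morph, , drop = FALSE]
  render_fmt <- function(conc, fmt, off) {
    render_spectra(conc, config$library, config$effects, seed = seed + off,
                   wn = config$wn, format = fmt,
                   background = config$background)
  }
  spectra <- list(
    whole_grain = render_fmt(chem, "whole_grain", 2L),
    whole_grain_flour = render_fmt(chem, "whole_grain_flour", 3L),
    hulled_flour = render_fmt(subset_chem("hulled"), "hulled_flour", 4L),
    hull_less_flour = render_fmt(subset_chem("hull_less"),
                                 "hull_less_flour", 5L)
  )
  structure(list(chemistry = chem, spectra = spectra, config = config),
            class = "sorghum_study")
}

#' @export
print.sorghum_study <- function(x, ...) {
  cat(sprintf("<sorghum_study: %d samples (%d hulled, %d hull-less), %d wavelengths>\n",
              nrow(x$chemistry),
              sum(x$chemistry$morphology == "hulled"),
              sum(x$chemistry$morphology == "hull_less"),
              length(wavenumbers(x$spectra[[1]]))))
  print(table(grade = x$chemistry$grade))
  invisible(x)
}

#' Extract one format of a simulated study as an aligned dataset
#'
#' @param study A `sorghum_study`.
#' @param format One of [sorghum_formats].
#' @return An `aligned_dataset` (see [align_dataset()]).
#' @export
study_dataset <- function(study, format = "whole_grain") {
  format <- match.arg(format, sorghum_formats)
  sp <- study$spectra[[format]]
  suppressWarnings(align_dataset(sp, study$chemistry))
}
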