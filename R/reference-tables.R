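# Published summary statistics for a 98-sample sorghum grain panel (20
# hybrids, two sites), scanned in four presentation formats. These tables are
# transcriptions of printed summaries, not measurements made by this package:
# they seed the synthetic generator and anchor the arithmetic self-checks
# (CV = 100*sd/mean, RPD = sd/RMSE).

#' Names of the eight grain biochemical components
#'
#' All concentrations in this package are in g kg^-1 dry matter.
#'
#' @export
sorghum_analytes <- c(
  "starch", "protein", "fat", "tannin",
  "cellulose", "hemicellulose", "lignin", "ash"
)

#' Names of the four sample presentation formats
#'
#' Whole grains and whole grain flours cover the full 98-sample panel
#' (the same grains scanned before and after milling); the hulled and
#' hull-less flour sets are the morphological subsets (61 and 37 samples).
#'
#' @export
sorghum_formats <- c(
  "whole_grain", "whole_grain_flour", "hulled_flour", "hull_less_flour"
)

# nocov start
.stats_block <- function(format, subset, n, min, max, mean, sd, cv) {
  tibble::tibble(
    format = format, subset = subset, n = n, analyte = sorghum_analytes,
    min = min, max = max, mean = mean, sd = sd, cv = cv
  )
}
# nocov end

#' Descriptive reference statistics of the sorghum panel
#'
#' Per-format, per-subset (calibration `"C"` / validation `"V"`) minimum,
#' maximum, mean, standard deviation and coefficient of variation (percent)
#' of the eight analytes, in g kg^-1. Whole-grain and whole-grain-flour rows
#' are identical because the same 98 grains were scanned in both formats.
#' These values are the defaults for [analyte_stats()] and the inputs of the
#' CV-arithmetic consistency checks.
#'
#' @return A tibble with columns `format`, `subset`, `n`, `analyte`, `min`,
#'   `max`, `mean`, `sd`, `cv`.
#' @export
#' @examples
#' sorghum_reference_stats()
sorghum_reference_stats <- function() {
  whole_c <- .stats_block(
    "whole_grain", "C", 73L,
    min  = c(298.67, 104.97, 13.99,  1.32,  62.64, 26.03, 27.10, 16.17),
    max  = c(784.79, 185.01, 58.99, 19.92, 216.86, 90.43, 87.68, 36.37),
    mean = c(589.24, 136.21, 36.83, 12.99, 116.17, 56.04, 56.78, 23.44),
    sd   = c( 98.25,  14.84,  8.95,  3.93,  30.27, 17.10, 16.17,  4.44),
    cv   = c( 16.67,  10.89, 24.32, 30.27,  26.06, 30.52, 28.48, 18.94)
  )
  whole_v <- .stats_block(
    "whole_grain", "V", 25L,
    min  = c(442.75, 113.14, 28.65, 12.21,  88.37, 32.27, 39.11, 17.73),
    max  = c(762.90, 160.67, 49.05, 17.06, 134.26, 87.89, 77.39, 32.33),
    mean = c(579.90, 136.50, 37.63, 14.95, 109.44, 64.55, 63.09, 25.17),
    sd   = c( 75.10,  13.18,  5.67,  1.35,  13.86, 13.83, 12.06,  3.52),
    cv   = c( 12.95,   9.66, 15.07,  9.08,  12.66, 21.42, 19.12, 14.00)
  )
  flour_c <- dplyr::mutate(whole_c, format = "whole_grain_flour")
  flour_v <- dplyr::mutate(whole_v, format = "whole_grain_flour")
  hulled_c <- .stats_block(
    "hulled_flour", "C", 45L,
    min  = c(376.98, 104.97, 13.99, 11.01,  75.84, 26.03, 31.39, 22.11),
    max  = c(744.38, 185.01, 58.99, 21.06, 181.85, 90.43, 87.68, 36.37),
    mean = c(546.95, 137.99, 36.41, 15.18, 113.30, 66.28, 67.90, 26.89),
    sd   = c( 71.57,  17.13,  9.64,  2.33,  19.96, 13.10, 10.95,  3.51),
    cv   = c( 13.08,  12.41, 26.48, 15.37,  17.62, 19.77, 16.13, 13.08)
  )
  hulled_v <- .stats_block(
    "hulled_flour", "V", 16L,
    min  = c(433.30, 120.96, 26.55, 12.56,  88.37, 51.72, 57.68, 22.17),
    max  = c(685.36, 165.23, 47.51, 16.61, 128.54, 87.96, 75.54, 31.71),
    mean = c(563.41, 138.10, 35.38, 14.78, 109.02, 64.31, 66.80, 24.79),
    sd   = c( 63.84,  12.86,  5.96,  1.09,  14.05,  9.38,  5.49,  2.22),
    cv   = c( 11.33,   9.31, 16.86,  7.43,  12.89, 14.59,  8.22,  8.97)
  )
  hull_less_c <- .stats_block(
    "hull_less_flour", "C", 27L,
    min  = c(519.91, 113.99, 21.97,  1.32,  62.64, 19.70, 22.03, 16.17),
    max  = c(784.79, 156.99, 53.18, 19.75, 216.86, 49.37, 57.03, 25.83),
    mean = c(645.06, 134.08, 37.81, 11.10, 120.07, 35.30, 39.40, 20.12),
    sd   = c( 77.75,  12.35,  7.55,  4.33,  38.30,  7.85,  7.44,  2.70),
    cv   = c( 12.05,   9.21, 19.97, 39.03,  31.89, 22.25, 18.90, 13.44)
  )
  hull_less_v <- .stats_block(
    "hull_less_flour", "V", 10L,
    min  = c(554.73, 123.34, 34.88,  4.16, 101.43, 28.23, 33.47, 17.44),
    max  = c(735.26, 146.47, 49.05, 15.62, 174.50, 46.44, 41.43, 23.11),
    mean = c(654.80, 133.47, 41.42, 12.34, 136.38, 35.44, 38.56, 19.75),
    sd   = c( 64.49,   7.37,  5.15,  3.87,  25.16,  5.44,  2.64,  1.74),
    cv   = c(  9.85,   5.52, 12.44, 31.36,  18.45, 15.35,  6.86,  8.82)
  )
  dplyr::bind_rows(
    whole_c, whole_v, flour_c, flour_v,
    hulled_c, hulled_v, hull_less_c, hull_less_v
  )
}

# nocov start
.bench_block <- function(format, analyte, pc, r2c, rmsec, sd_cal,
                         r2cv, rmsecv, rpd_cv, r2v, rmsev, rpd_v, sd_val) {
  tibble::tibble(
    format = format, analyte = analyte, pc = pc,
    r2c = r2c, rmsec = rmsec, sd_cal = sd_cal,
    r2cv = r2cv, rmsecv = rmsecv, rpd_cv = rpd_cv,
    r2v = r2v, rmsev = rmsev, rpd_v = rpd_v, sd_val = sd_val
  )
}
# nocov end

#' Published PLSR benchmark statistics of the sorghum panel
#'
#' Calibration / cross-validation / validation statistics of the published
#' per-format, per-analyte PLSR models: latent-variable count (`pc`), R^2,
#' RMSE and subset standard deviations. Used only as arithmetic anchors
#' (RPD = sd/RMSE) and for context; the package never fits to these numbers.
#' The whole-grain-flour ash row duplicates the protein row in the printed
#' source (a typesetting artifact) and is excluded from consistency checks.
#'
#' @return A tibble with one row per format x analyte.
#' @export
sorghum_model_benchmarks <- function() {
  a <- sorghum_analytes
  dplyr::bind_rows(
    .bench_block("whole_grain", a,
      pc     = c(8, 8, 8, 7, 8, 9, 7, 6),
      r2c    = c(0.98, 0.97, 0.98, 0.98, 0.99, 0.99, 0.97, 0.98),
      rmsec  = c(10.90, 2.12, 1.06, 0.04, 1.45, 0.47, 2.55, 0.54),
      sd_cal = c(98.25, 14.84, 8.95, 0.39, 27.03, 17.10, 16.17, 4.44),
      r2cv   = c(0.92, 0.90, 0.91, 0.93, 0.96, 0.98, 0.94, 0.94),
      rmsecv = c(26.29, 4.65, 2.56, 0.09, 4.89, 1.96, 3.75, 1.00),
      rpd_cv = c(3.73, 3.18, 3.48, 3.96, 5.52, 8.69, 4.31, 4.43),
      r2v    = c(0.88, 0.89, 0.91, 0.72, 0.88, 0.97, 0.93, 0.93),
      rmsev  = c(24.94, 4.23, 1.76, 0.06, 4.68, 2.23, 3.07, 0.88),
      rpd_v  = c(3.01, 3.11, 3.21, 1.94, 2.96, 6.18, 3.91, 3.96),
      sd_val = c(75.10, 13.18, 5.67, 0.13, 13.86, 13.83, 12.06, 3.52)
    ),
    .bench_block("whole_grain_flour", a,
      pc     = c(6, 5, 9, 7, 7, 8, 8, 5),
      r2c    = c(0.96, 0.98, 0.97, 0.96, 0.99, 0.99, 0.99, 0.98),
      rmsec  = c(16.83, 2.05, 1.22, 0.07, 2.04, 1.29, 0.76, 2.05),
      sd_cal = c(96.32, 15.09, 8.00, 0.38, 25.83, 16.88, 16.08, 15.09),
      r2cv   = c(0.91, 0.96, 0.84, 0.91, 0.94, 0.97, 0.98, 0.96),
      rmsecv = c(28.60, 2.88, 3.14, 0.86, 6.14, 2.70, 1.91, 2.88),
      rpd_cv = c(3.36, 5.23, 2.54, 2.73, 4.20, 6.23, 8.39, 5.23),
      r2v    = c(0.90, 0.96, 0.90, 0.91, 0.92, 0.99, 0.97, 0.96),
      rmsev  = c(23.01, 2.37, 2.68, 0.09, 5.91, 2.44, 1.97, 2.37),
      rpd_v  = c(3.05, 5.35, 3.17, 3.27, 3.58, 6.89, 6.92, 5.35),
      sd_val = c(70.37, 12.73, 8.53, 0.30, 21.20, 16.84, 13.65, 12.73)
    ),
    .bench_block("hulled_flour", a,
      pc     = c(6, 8, 6, 8, 9, 9, 7, 7),
      r2c    = c(0.99, 0.99, 0.98, 0.99, 0.99, 0.99, 0.99, 0.99),
      rmsec  = c(6.75, 1.09, 0.10, 0.01, 1.54, 0.73, 0.87, 0.31),
      sd_cal = c(71.57, 17.13, 0.96, 0.23, 19.96, 11.71, 9.54, 3.51),
      r2cv   = c(0.96, 0.98, 0.92, 0.94, 0.93, 0.96, 0.94, 0.96),
      rmsecv = c(13.29, 2.14, 0.27, 0.05, 4.91, 2.24, 2.22, 0.66),
      rpd_cv = c(5.38, 7.97, 3.48, 4.32, 4.05, 5.21, 4.28, 5.33),
      r2v    = c(0.92, 0.98, 0.93, 0.90, 0.90, 0.93, 0.95, 0.97),
      rmsev  = c(18.61, 1.79, 0.16, 0.04, 4.25, 2.75, 1.40, 0.40),
      rpd_v  = c(3.42, 7.17, 3.62, 2.74, 3.30, 3.40, 3.91, 5.56),
      sd_val = c(63.84, 12.86, 0.59, 0.10, 14.05, 9.38, 5.49, 2.22)
    ),
    .bench_block("hull_less_flour", a,
      pc     = c(5, 6, 9, 8, 9, 9, 7, 6),
      r2c    = c(0.97, 0.99, 0.99, 0.97, 0.99, 0.99, 0.99, 0.98),
      rmsec  = c(1.24, 1.11, 0.01, 0.06, 1.04, 0.17, 0.31, 0.32),
      sd_cal = c(7.90, 12.35, 0.75, 0.44, 38.30, 7.85, 7.44, 2.70),
      r2cv   = c(0.88, 0.97, 0.97, 0.90, 0.97, 0.98, 0.98, 0.93),
      rmsecv = c(2.62, 2.06, 0.11, 0.13, 5.79, 1.08, 1.08, 0.68),
      rpd_cv = c(3.01, 5.98, 6.48, 3.36, 6.61, 7.26, 6.87, 3.94),
      r2v    = c(0.93, 0.94, 0.97, 0.99, 0.97, 0.97, 0.97, 0.88),
      rmsev  = c(1.57, 1.85, 0.08, 0.04, 4.11, 0.92, 0.47, 0.60),
      rpd_v  = c(3.92, 3.97, 6.28, 8.46, 6.11, 5.86, 5.55, 2.88),
      sd_val = c(6.19, 7.37, 0.51, 0.38, 25.16, 5.44, 2.64, 1.74)
    )
  )
}

#' Default per-model preprocessing and partitioning recipes
#'
#' The published best treatment per format x analyte: scatter correction
#' (MSC or SNV), Savitzky-Golay smoothing (nominally "52 points", shipped as
#' the nearest odd symmetric window of 51, polynomial order 2), derivative
#' order, CARS variable selection, and the sample-partitioning method
#' (Kennard-Stone or SPXY). [run_pipeline()] uses these unless overridden.
#'
#' @return A tibble with columns `format`, `analyte`, `scatter`, `window`,
#'   `polyorder`, `derivative`, `split_method`.
#' @export
default_recipes <- function() {
  rec <- function(format, scatter, derivative, split_method) {
    tibble::tibble(
      format = format, analyte = sorghum_analytes, scatter = scatter,
      window = 51L, polyorder = 2L, derivative = as.integer(derivative),
      split_method = split_method
    )
  }
  dplyr::bind_rows(
    rec("whole_grain",
        c("msc", "msc", "snv", "snv", "snv", "msc", "snv", "msc"),
        c(2, 2, 2, 2, 2, 2, 1, 2),
        c("spxy", "spxy", "spxy", "spxy", "spxy", "spxy", "ks", "spxy")),
    rec("whole_grain_flour",
        c("snv", "msc", "msc", "snv", "snv", "snv", "msc", "msc"),
        c(2, 2, 2, 2, 2, 2, 2, 2),
        c("ks", "spxy", "ks", "ks", "spxy", "spxy", "spxy", "spxy")),
    rec("hulled_flour",
        c("msc", "snv", "snv", "msc", "msc", "snv", "snv", "msc"),
        c(2, 2, 2, 2, 2, 2, 2, 2),
        c("spxy", "spxy", "ks", "spxy", "ks", "spxy", "spxy", "spxy")),
    rec("hull_less_flour",
        c("msc", "snv", "snv", "snv", "msc", "snv", "msc", "msc"),
        c(1, 1, 2, 1, 2, 2, 2, 1),
        c("spxy", "spxy", "spxy", "spxy", "ks", "spxy", "spxy", "spxy"))
  )
}
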