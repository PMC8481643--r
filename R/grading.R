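# Composition formulas and the food/feed/fuel decision table.

#' NREL composition from acid-hydrolysis sugars and lignin fractions
#'
#' Anhydro-corrections of the two-stage acid-hydrolysis assay:
#' cellulose = 0.9 x glucose, hemicellulose = 0.88 x (xylose + arabinose),
#' lignin = acid-soluble + acid-insoluble lignin. The 0.88 pentose
#' correction is applied to the xylose + arabinose sum, the standard
#' anhydro convention. All units g kg^-1.
#'
#' @param glucose,xylose,arabinose,acid_soluble_lignin,acid_insoluble_lignin
#'   Non-negative assay values in g kg^-1 (vectorized).
#' @return Tibble with columns `cellulose`, `hemicellulose`, `lignin`.
#' @export
#' @examples
#' nrel_composition(100, 50, 10, 10, 40)
nrel_composition <- function(glucose, xylose, arabinose,
                             acid_soluble_lignin, acid_insoluble_lignin) {
  vals <- cbind(glucose, xylose, arabinose,
                acid_soluble_lignin, acid_insoluble_lignin)
  if (any(vals < 0)) abort("Assay inputs must be >= 0.")
  tibble::tibble(
    cellulose = 0.9 * glucose,
    hemicellulose = 0.88 * (xylose + arabinose),
    lignin = acid_soluble_lignin + acid_insoluble_lignin
  )
}

#' Grading thresholds
#'
#' Tannin >= 15 g kg^-1 (1.5%) and hemicellulose >= 50 g kg^-1 (5%) route
#' a grain to fuel; starch >= 650 g kg^-1 (65%) separates food from feed
#' among the low-tannin, low-hemicellulose grains.
#'
#' @param tannin_fuel Tannin threshold, g kg^-1.
#' @param hemicellulose_fuel Hemicellulose threshold, g kg^-1.
#' @param starch_food Starch threshold, g kg^-1.
#' @return A `grading_rules` list.
#' @export
grading_rules <- function(tannin_fuel = 15, hemicellulose_fuel = 50,
                          starch_food = 650) {
  if (tannin_fuel <= 0 || hemicellulose_fuel <= 0 || starch_food <= 0) {
    abort("Thresholds must be > 0.")
  }
  structure(
    list(tannin_fuel = tannin_fuel, hemicellulose_fuel = hemicellulose_fuel,
         starch_food = starch_food),
    class = "grading_rules"
  )
}

#' Grade labels
#' @export
grade_levels <- c("food", "feed", "fuel", "feed_fuel")

#' Grade a grain sample for food, feed or fuel use
#'
#' Decision table (boundaries are "equal or more than", i.e. `>=`):
#' * tannin >= 15 and hemicellulose >= 50 -> `fuel`
#' * tannin >= 15 and hemicellulose <  50 -> `fuel` (conservative: high
#'   tannin disqualifies food and feed regardless of fiber)
#' * tannin <  15 and hemicellulose >= 50 -> `feed_fuel` (low tannin suits
#'   feed, high hemicellulose suits fuel; reconstructed combined class)
#' * tannin <  15 and hemicellulose <  50 and starch >= 650 -> `food`
#' * tannin <  15 and hemicellulose <  50 and starch <  650 -> `feed`
#'
#' Every non-negative triple maps to exactly one label.
#'
#' @param tannin,hemicellulose,starch Concentrations in g kg^-1 (vectorized).
#' @param rules A [grading_rules()].
#' @return Factor with levels [grade_levels].
#' @export
#' @examples
#' grade_sample(15.18, 66.28, 546.95)  # fuel
#' grade_sample(11.66, 29.92, 695.57)  # food
grade_sample <- function(tannin, hemicellulose, starch,
                         rules = grading_rules()) {
  if (any(c(tannin, hemicellulose, starch) < 0)) {
    abort("Concentrations must be >= 0.")
  }
  hi_tan <- tannin >= rules$tannin_fuel
  hi_hemi <- hemicellulose >= rules$hemicellulose_fuel
  hi_starch <- starch >= rules$starch_food
  out <- ifelse(hi_tan, "fuel",
         ifelse(hi_hemi, "feed_fuel",
         ifelse(hi_starch, "food", "feed")))
  factor(out, levels = grade_levels)
}
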