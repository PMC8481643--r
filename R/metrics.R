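# Model performance metrics: RPD, CV%, the adequacy rating bands, the
# paired t-test of prediction accuracy, and the full model report.

#' Ratio of performance to deviation
#'
#' `RPD = SD / RMSE`: the spread of the reference values divided by the
#' prediction error. RPD > 4 marks an efficient model, 1.75-2.25 a model
#' good only for preliminary screening.
#'
#' @param sd Reference standard deviation (n-1 denominator).
#' @param rmse Root mean square error, `> 0`.
#' @return `sd / rmse`.
#' @export
#' @examples
#' rpd(75.10, 24.94)  # 3.01
rpd <- function(sd, rmse) {
  if (any(rmse <= 0)) {
    abort("`rmse` must be > 0; an RMSE of 0 is an exact fit (RPD undefined).")
  }
  sd / rmse
}

#' Coefficient of variation in percent
#'
#' @param mean Mean value (nonzero).
#' @param sd Standard deviation.
#' @return `100 * sd / mean`.
#' @export
#' @examples
#' cv_percent(589.24, 98.25)  # 16.67
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) abort("`mean` must be nonzero for a CV.")
  100 * sd / mean
}

.rating_levels <- c("inadequate", "preliminary", "satisfactory",
                    "successful", "efficient")

#' Rate a calibration model from its R^2 and RPD
#'
#' Adequacy bands: R^2 > 0.95 and RPD > 4 predict efficiently;
#' 0.9 < R^2 <= 0.95 and 3 < RPD <= 4 is a successful calibration;
#' 0.8 < R^2 <= 0.9 and 2.25 < RPD <= 3 is satisfactory;
#' 0.7 < R^2 <= 0.8 and 1.75 < RPD <= 2.25 is good for preliminary
#' screening; below both floors the model is inadequate. When R^2 and RPD
#' fall in different bands the lower (more conservative) one is returned.
#'
#' @param r2 Determination coefficient in `[0, 1]`.
#' @param rpd RPD value, `> 0` (may be `Inf` for an exact fit).
#' @return Ordered factor with levels inadequate < preliminary <
#'   satisfactory < successful < efficient.
#' @export
#' @examples
#' rate_model(0.97, 6.18)  # efficient
#' rate_model(0.72, 1.94)  # preliminary
rate_model <- function(r2, rpd) {
  if (any(r2 < 0 | r2 > 1)) abort("`r2` must lie in [0, 1].")
  if (any(rpd <= 0)) abort("`rpd` must be > 0.")
  tier_r2 <- findInterval(r2, c(0.7, 0.8, 0.9, 0.95), left.open = TRUE)
  tier_rpd <- findInterval(rpd, c(1.75, 2.25, 3, 4), left.open = TRUE)
  factor(.rating_levels[pmin(tier_r2, tier_rpd) + 1L],
         levels = .rating_levels, ordered = TRUE)
}

#' Paired t-test of measured versus predicted values
#'
#' Classic paired t on the differences, df = n - 1, two-sided p.
#'
#' @param measured,predicted Equal-length numeric vectors, n >= 3.
#' @return A tibble with `t`, `df`, `p_value`. Zero-variance differences
#'   give t = 0, p = 1 when the mean difference is zero, otherwise an
#'   infinite t with p = 0.
#' @export
paired_t <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 3L) {
    abort("Need equal-length vectors with n >= 3.")
  }
  d <- measured - predicted
  n <- length(d)
  s <- sd(d)
  if (s < 1e-14) {
    if (abs(mean(d)) < 1e-14) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(d)) * Inf; p <- 0
    }
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- 2 * pt(-abs(t), df = n - 1)
  }
  tibble::tibble(t = t, df = n - 1L, p_value = p)
}

.r2 <- function(obs, pred, method = c("correlation", "sse")) {
  method <- match.arg(method)
  if (method == "correlation") {
    if (sd(pred) < 1e-14 || sd(obs) < 1e-14) return(0)
    cor(obs, pred)^2
  } else {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  }
}

#' Evaluate a fitted PLS model on calibration and validation subsets
#'
#' Produces the full report used in the published summaries: calibration
#' R^2/RMSE/SD, cross-validation R^2 (from the RMSECV curve)/RMSECV/RPDcv,
#' validation R^2/RMSEv/RPDv/SD, plus the paired t of measured vs predicted
#' validation values. R^2 is the squared Pearson correlation of predicted
#' versus measured (the scatter-plot convention); `r2_method = "sse"` gives
#' the 1 - SSE/SST alternative. RPD denominators are the corresponding
#' subset standard deviations (n-1).
#'
#' @param model A `pls_model` fitted on `(X_cal, y_cal)`.
#' @param X_cal,y_cal Calibration data.
#' @param X_val,y_val Validation data (n >= 3).
#' @param cv Result of [loocv_select()] on the calibration data (optional;
#'   cross-validation fields are `NA` when omitted).
#' @param r2_method `"correlation"` (default) or `"sse"`.
#' @return A `model_report` (tibble row) with fields `n_lv`, `r2c`, `rmsec`,
#'   `sd_cal`, `r2cv`, `rmsecv`, `rpd_cv`, `r2v`, `rmsev`, `rpd_v`,
#'   `sd_val`, `rating`, `t`, `p_value`, `exact_fit`.
#' @export
evaluate_model <- function(model, X_cal, y_cal, X_val, y_val, cv = NULL,
                           r2_method = c("correlation", "sse")) {
  r2_method <- match.arg(r2_method)
  if (length(y_val) < 3L) abort("Validation subset must have n >= 3.")
  pred_cal <- predict(model, X_cal)
  pred_val <- predict(model, X_val)
  rmsec <- sqrt(mean((pred_cal - y_cal)^2))
  rmsev <- sqrt(mean((pred_val - y_val)^2))
  sd_cal <- sd(y_cal)
  sd_val <- sd(y_val)
  rmsecv <- NA_real_
  r2cv <- NA_real_
  if (!is.null(cv)) {
    h <- min(model$n_lv, length(cv$rmsecv))
    rmsecv <- cv$rmsecv[h]
    if (!is.null(cv$predictions)) {
      r2cv <- .r2(y_cal, cv$predictions[, h], r2_method)
    }
  }
  exact <- rmsev < 1e-12
  rpd_v <- if (exact) Inf else rpd(sd_val, rmsev)
  rpd_cv <- if (is.na(rmsecv)) NA_real_
            else if (rmsecv < 1e-12) Inf else rpd(sd_cal, rmsecv)
  r2v <- .r2(y_val, pred_val, r2_method)
  r2c <- .r2(y_cal, pred_cal, r2_method)
  tt <- paired_t(y_val, pred_val)
  out <- tibble::tibble(
    n_lv = model$n_lv,
    r2c = r2c, rmsec = rmsec, sd_cal = sd_cal,
    r2cv = r2cv, rmsecv = rmsecv, rpd_cv = rpd_cv,
    r2v = r2v, rmsev = rmsev, rpd_v = rpd_v, sd_val = sd_val,
    rating = rate_model(min(max(r2v, 0), 1), max(rpd_v, .Machine$double.eps)),
    t = tt$t, p_value = tt$p_value,
    exact_fit = exact
  )
  class(out) <- c("model_report", class(out))
  out
}

#' @exportS3Method
glance.model_report <- function(x, ...) {
  tibble::as_tibble(x)[, c("n_lv", "r2c", "r2v", "rpd_v", "rating")]
}
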