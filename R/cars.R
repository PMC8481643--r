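# Competitive adaptive reweighted sampling (CARS) wavelength selection.
# Each sampling run fits a PLS model on a Monte-Carlo subset of the
# calibration samples, cuts variables to an exponentially decreasing
# fraction of p by |regression coefficient| (the forced reduction), thins
# the survivors by coefficient-weighted resampling (ARS), and records the
# RMSECV of the resulting variable set on the full calibration data. The
# run with minimal RMSECV wins.

#' Exponentially decreasing retention fraction (EDF)
#'
#' `r_i = a * exp(-k * i)` with `a = (p/2)^(1/(N-1))` and
#' `k = log(p/2)/(N-1)`, so that `r_1 = 1` (all variables survive the first
#' run) and `r_N = 2/p` (two variables survive the last).
#'
#' @param i Run index, `1..N` (vectorized).
#' @param N Total number of sampling runs, `>= 2`.
#' @param p Total number of variables, `>= 2`.
#' @return Fraction(s) of the `p` variables retained at run `i`.
#' @export
#' @examples
#' edf_ratio(1, 50, 500)   # 1
#' edf_ratio(50, 50, 100)  # 2/100
edf_ratio <- function(i, N, p) {
  if (p < 2) abort("`p` must be >= 2.")
  if (N < 2) abort("`N` must be >= 2.")
  if (any(i < 1 | i > N)) abort("`i` must lie in 1..N.")
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  a * exp(-k * i)
}

#' CARS configuration
#'
#' @param runs Number of sampling runs `N` (default 50).
#' @param fraction Monte-Carlo fraction of calibration samples fitted per
#'   run (default 0.8).
#' @param folds Folds for the per-run RMSECV; `NULL` = leave-one-out.
#'   `folds = 5` or `10` is much faster and usually indistinguishable.
#' @param max_lv Latent variables used inside every run (fixed, not
#'   re-optimized per run, for determinism and speed).
#' @param seed Integer seed making the whole selection reproducible.
#' @return A `cars_config` list.
#' @export
cars_config <- function(runs = 50L, fraction = 0.8, folds = NULL,
                        max_lv = 10L, seed = 1L) {
  if (runs < 2L) abort("`runs` must be >= 2.")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  structure(
    list(runs = as.integer(runs), fraction = fraction, folds = folds,
         max_lv = as.integer(max_lv), seed = as.integer(seed)),
    class = "cars_config"
  )
}

#' Competitive adaptive reweighted sampling
#'
#' Runs CARS on calibration data only (never let validation samples leak in)
#' and returns the winning variable subset.
#'
#' @param X Calibration matrix (samples x variables), `p >= 2`.
#' @param y Analyte vector.
#' @param config A [cars_config()].
#' @return A `cars_result`: `selected` (winning variable indices, ascending),
#'   `best_run`, and `runs` (tibble with per-run retained count, RMSECV and
#'   the retained variable sets as a list-column).
#' @export
cars <- function(X, y, config = cars_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) abort("CARS needs at least 2 variables.")
  if (sd(y) < 1e-14) abort("`y` is constant; CARS target undefined.")
  N <- config$runs
  withr::with_seed(config$seed, {
    retained <- seq_len(p)
    run_vars <- vector("list", N)
    run_rmsecv <- numeric(N)
    run_kept <- integer(N)
    for (i in seq_len(N)) {
      sub <- sort(sample.int(n, max(2L, ceiling(config$fraction * n))))
      n_lv <- min(config$max_lv, length(sub) - 1L, length(retained))
      fit <- .pls_core(X[sub, retained, drop = FALSE], y[sub], n_lv)
      coef_abs <- abs(as.vector(fit$R %*% fit$q))
      # forced reduction: top ceil(r_i * p) of the retained set
      k_i <- max(2L, min(length(retained), ceiling(edf_ratio(i, N, p) * p)))
      keep <- order(coef_abs, decreasing = TRUE)[seq_len(k_i)]
      retained <- retained[keep]
      coef_abs <- coef_abs[keep]
      # adaptive reweighted sampling: k_i weighted draws with replacement,
      # realized as the unique set drawn
      if (all(coef_abs == 0)) coef_abs <- coef_abs + 1
      drawn <- unique(sample(seq_along(retained), size = k_i,
                             replace = TRUE, prob = coef_abs))
      if (length(drawn) < 2L) {
        drawn <- order(coef_abs, decreasing = TRUE)[1:2]
      }
      retained <- sort(retained[drawn])
      run_vars[[i]] <- retained
      run_kept[i] <- length(retained)
      cv <- pls_cv_curve(X[, retained, drop = FALSE], y,
                         max_lv = min(config$max_lv, n - 2L, length(retained)),
                         folds = config$folds, seed = config$seed + i)
      run_rmsecv[i] <- min(cv)
    }
    best <- which.min(run_rmsecv)
    structure(
      list(
        selected = run_vars[[best]],
        best_run = best,
        runs = tibble::tibble(
          run = seq_len(N),
          n_retained = run_kept,
          rmsecv = run_rmsecv,
          variables = run_vars
        )
      ),
      class = "cars_result"
    )
  })
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result: %d variables selected at run %d (RMSECV %.4g)>\n",
              length(x$selected), x$best_run, min(x$runs$rmsecv)))
  invisible(x)
}

#' @exportS3Method
tidy.cars_result <- function(x, ...) {
  dplyr::select(x$runs, "run", "n_retained", "rmsecv")
}

#' @exportS3Method
autoplot.cars_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rmsecv)) +
    ggplot2::geom_point(
      data = df[object$best_run, ],
      ggplot2::aes(y = .data$rmsecv), colour = "red", size = 2
    ) +
    ggplot2::labs(x = "sampling run", y = "RMSECV",
                  title = "CARS retention path (red = winning run)")
}
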