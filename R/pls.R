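# NIPALS partial least squares regression (single response). For one y the
# NIPALS weight update needs no inner iteration: w_h = E'f / ||E'f||.
# X and y are mean-centered internally; no scaling.

.pls_core <- function(X, y, n_lv) {
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  Tm <- matrix(0, n, n_lv)
  h_used <- 0L
  for (h in seq_len(n_lv)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break              # y fully deflated: stop early
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-28) break
    p_h <- crossprod(E, t) / tt
    q_h <- sum(f * t) / tt
    E <- E - tcrossprod(t, p_h)
    f <- f - q_h * t
    W[, h] <- w; P[, h] <- p_h; q[h] <- q_h; Tm[, h] <- t
    h_used <- h
  }
  if (h_used == 0L) abort("PLS found no usable component (zero covariance).")
  W <- W[, seq_len(h_used), drop = FALSE]
  P <- P[, seq_len(h_used), drop = FALSE]
  q <- q[seq_len(h_used)]
  # R = W (P'W)^-1 maps original centered X to scores; beta = R q
  R <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, q = q, R = R, scores = Tm[, seq_len(h_used), drop = FALSE],
       x_mean = x_mean, y_mean = y_mean, n_lv = h_used)
}

#' Fit a PLS1 regression by NIPALS
#'
#' @param X Calibration matrix (samples x variables), mean-centered
#'   internally.
#' @param y Analyte vector (g kg^-1).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n-1, p)`.
#' @return A `pls_model`: weights `W`, loadings `P`, y-loadings `q`,
#'   regression coefficients on the original variables, centering vectors
#'   and the latent-variable count actually used (early stop if y deflates
#'   to numerical zero).
#' @export
fit_pls <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("`y` must have one value per row of `X`.")
  if (anyNA(X) || any(!is.finite(X)) || anyNA(y) || any(!is.finite(y))) {
    abort("`X` and `y` must be finite.")
  }
  if (n_lv < 1L || n_lv > min(n - 1L, p)) {
    abort(sprintf("`n_lv` must be in 1..min(n-1, p) = 1..%d.", min(n - 1L, p)))
  }
  if (sd(y) < 1e-14) abort("`y` has (numerically) zero variance.")
  core <- .pls_core(X, y, as.integer(n_lv))
  structure(
    list(n_lv = core$n_lv, weights = core$W, x_loadings = core$P,
         y_loadings = core$q, coefficients = as.vector(core$R %*% core$q),
         x_mean = core$x_mean, y_mean = core$y_mean,
         n_samples = n, n_vars = p),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d latent variables, %d variables, n = %d>\n",
              x$n_lv, x$n_vars, x$n_samples))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' Applies the stored centering and regression coefficients; no refitting.
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the same variables as the calibration matrix.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_vars) {
    abort(sprintf("`newdata` has %d variables; model expects %d.",
                  ncol(newdata), object$n_vars))
  }
  as.vector(object$y_mean +
              sweep(newdata, 2, object$x_mean) %*% object$coefficients)
}

# Predictions on new rows for every component count 1..n_lv of one fit.
# Scores are computed by sequential deflation with the stored W and P.
.pls_predict_path <- function(core, X_new) {
  Ec <- sweep(as.matrix(X_new), 2, core$x_mean)
  n_lv <- core$n_lv
  preds <- matrix(core$y_mean, nrow(Ec), n_lv)
  acc <- rep(core$y_mean, nrow(Ec))
  for (h in seq_len(n_lv)) {
    t_h <- as.vector(Ec %*% core$W[, h])
    Ec <- Ec - tcrossprod(t_h, core$P[, h])
    acc <- acc + core$q[h] * t_h
    preds[, h] <- acc
  }
  preds
}

#' Cross-validated RMSE of a PLS model
#'
#' K-fold (or leave-one-out) cross-validation, returning the RMSECV for
#' every component count `1..max_lv` from a single fit per fold.
#'
#' @param X,y Calibration data.
#' @param max_lv Largest latent-variable count to evaluate.
#' @param folds Number of folds; `NULL` (default) = leave-one-out.
#' @param seed Optional seed controlling the fold assignment (ignored for
#'   leave-one-out, which is deterministic).
#' @return Numeric vector of RMSECV values, one per component count. Fewer
#'   than `max_lv` entries can be returned if every fold stops early.
#' @export
pls_cv_curve <- function(X, y, max_lv, folds = NULL, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) abort("Cross-validation needs n >= 3.")
  max_lv <- as.integer(max_lv)
  if (max_lv < 1L || max_lv > min(n - 2L, ncol(X))) {
    abort("`max_lv` must be in 1..min(n-2, p).")
  }
  if (is.null(folds) || folds >= n) {
    assign_f <- seq_len(n)
    k <- n
  } else {
    k <- as.integer(folds)
    if (k < 2L) abort("`folds` must be >= 2.")
    idx <- seq_len(n)
    if (!is.null(seed)) {
      idx <- withr::with_seed(seed, sample.int(n))
    }
    assign_f <- integer(n)
    assign_f[idx] <- rep_len(seq_len(k), n)
  }
  pred <- matrix(NA_real_, n, max_lv)
  for (f in seq_len(k)) {
    test <- which(assign_f == f)
    train <- setdiff(seq_len(n), test)
    core <- .pls_core(X[train, , drop = FALSE], y[train],
                      min(max_lv, length(train) - 1L, ncol(X)))
    path <- .pls_predict_path(core, X[test, , drop = FALSE])
    got <- ncol(path)
    pred[test, seq_len(got)] <- path
    if (got < max_lv) {
      pred[test, (got + 1L):max_lv] <- path[, got]   # early stop: carry last
    }
  }
  out <- sqrt(colMeans((pred - y)^2))
  attr(out, "predictions") <- pred
  out
}

#' Choose the latent-variable count by leave-one-out cross-validation
#'
#' Computes the RMSECV curve for `1..max_lv` components and applies the
#' parsimony rule: the chosen count is the smallest whose RMSECV is within
#' `tol` (default 2%) of the curve minimum.
#'
#' @inheritParams pls_cv_curve
#' @param tol Relative parsimony tolerance on the RMSECV minimum.
#' @param folds `NULL` for leave-one-out (the default and the published
#'   choice); an integer >= 2 for k-fold.
#' @return List with `n_lv` (chosen) and `rmsecv` (the full curve).
#' @export
loocv_select <- function(X, y, max_lv, tol = 0.02, folds = NULL, seed = NULL) {
  curve <- pls_cv_curve(X, y, max_lv, folds = folds, seed = seed)
  best <- min(curve)
  chosen <- which(curve <= (1 + tol) * best)[1]
  list(n_lv = as.integer(chosen), rmsecv = as.numeric(curve),
       predictions = attr(curve, "predictions"))
}

#' @exportS3Method
tidy.pls_model <- function(x, ...) {
  tibble::tibble(
    term = paste0("V", seq_len(x$n_vars)),
    estimate = x$coefficients
  )
}

#' @exportS3Method
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, n_vars = x$n_vars, n_samples = x$n_samples)
}
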