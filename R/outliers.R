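# PCA score-space outlier screening: a chi-square(2) confidence ellipse on
# the variance-standardized first two principal-component scores, with
# iterative one-at-a-time removal of the worst sample.

#' Principal component scores of a spectra matrix
#'
#' Column-mean-centered PCA (no scaling), as used for score-plot outlier
#' maps.
#'
#' @param x Treated absorbance matrix or `nir_spectra`, `n >= 3`.
#' @param n_components Number of components, `<= min(n-1, p)`.
#' @return List with `scores` (n x n_components, orthogonal columns),
#'   `variance_explained` (fractions, non-increasing) and `loadings`.
#' @export
pca_scores <- function(x, n_components = 2L) {
  m <- .pre_matrix(x)
  n <- nrow(m)
  if (n < 3L) abort("PCA screening needs n >= 3.")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, ncol(m))) {
    abort("`n_components` must be in 1..min(n-1, p).")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  list(
    scores = pc$x[, seq_len(n_components), drop = FALSE],
    variance_explained =
      (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
    loadings = pc$rotation[, seq_len(n_components), drop = FALSE]
  )
}

#' Screen spectral outliers on the first two principal components
#'
#' Iteratively: compute 2-component PCA scores, standardize each column by
#' its standard deviation, and flag samples whose squared Mahalanobis-type
#' distance `T^2 = z1^2 + z2^2` exceeds the chi-square(2) quantile at
#' `alpha` (5.991 at 0.95). The single worst flagged sample is removed and
#' the PCA refitted, matching the practice of removing score-plot outliers
#' individually. Stops when nothing is flagged, `max_removals` is reached,
#' or half of the input would be gone (hard floor, with a warning).
#'
#' @param x Treated absorbance matrix or `nir_spectra`, `n >= 10`
#'   recommended (a warning is raised below).
#' @param alpha Confidence level in (0, 1); default 0.95.
#' @param max_removals Cap on removed samples (default unlimited).
#' @return An `outlier_report`: `kept` (indices), `removed` (tibble of
#'   index, statistic, iteration), `limit`, `n_input`, and
#'   `first_pass_flagged` (how many samples exceeded the limit on the
#'   initial, full-data pass — the coverage diagnostic).
#' @export
screen_outliers <- function(x, alpha = 0.95, max_removals = Inf) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  m <- .pre_matrix(x)
  n <- nrow(m)
  if (n < 10L) warn("Outlier screening on fewer than 10 samples is fragile.")
  limit <- qchisq(alpha, df = 2)
  floor_n <- ceiling(n / 2)
  kept <- seq_len(n)
  sc0 <- pca_scores(m, 2L)$scores
  z0 <- sweep(sc0, 2, apply(sc0, 2, sd), "/")
  first_pass_flagged <- sum(rowSums(z0^2) > limit)
  removed <- tibble::tibble(index = integer(), statistic = numeric(),
                            iteration = integer())
  iter <- 0L
  while (nrow(removed) < max_removals) {
    if (length(kept) <= floor_n) {
      if (iter > 0L) warn("Outlier screening stopped at the 50% floor.")
      break
    }
    iter <- iter + 1L
    sc <- pca_scores(m[kept, , drop = FALSE], 2L)$scores
    z <- sweep(sc, 2, apply(sc, 2, sd), "/")
    t2 <- rowSums(z^2)
    flagged <- which(t2 > limit)
    if (length(flagged) == 0L) break
    worst <- flagged[which.max(t2[flagged])]
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      index = kept[worst], statistic = t2[worst], iteration = iter
    ))
    kept <- kept[-worst]
  }
  structure(
    list(kept = kept, removed = removed, limit = limit, n_input = n,
         alpha = alpha, first_pass_flagged = first_pass_flagged),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report: %d kept, %d removed (T^2 limit %.3f at alpha %.2f)>\n",
    length(x$kept), nrow(x$removed), x$limit, x$alpha))
  invisible(x)
}

#' @exportS3Method
tidy.outlier_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(index = x$kept, status = "kept",
                   statistic = NA_real_, iteration = NA_integer_),
    dplyr::mutate(x$removed, status = "removed")
  )
}
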