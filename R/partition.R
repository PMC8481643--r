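# Deterministic calibration/validation partitioning. Both algorithms are
# greedy maximin selections on a distance matrix; SPXY augments the spectral
# distance with the analyte distance, each normalized by its maximum.

.greedy_maximin <- function(D, n_cal) {
  n <- nrow(D)
  if (n_cal < 2L || n_cal >= n) {
    abort("`n_cal` must satisfy 2 <= n_cal < n.")
  }
  # seed pair: maximal distance, ties broken by lowest (i, j) index pair
  best <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] > best_d + 1e-15) {
        best <- c(i, j); best_d <- D[i, j]
      }
    }
  }
  selected <- best
  candidates <- setdiff(seq_len(n), selected)
  while (length(selected) < n_cal) {
    mind <- apply(D[candidates, selected, drop = FALSE], 1, min)
    pick <- candidates[which.max(mind + 0)]   # which.max: first max = lowest index
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
  }
  selected
}

.new_split <- function(order, n, method) {
  structure(
    list(calibration = sort(order), validation = setdiff(seq_len(n), order),
         method = method, order = order),
    class = "sample_split"
  )
}

#' @export
print.sample_split <- function(x, ...) {
  cat(sprintf("<sample_split [%s]: %d calibration / %d validation>\n",
              x$method, length(x$calibration), length(x$validation)))
  invisible(x)
}

#' Kennard-Stone calibration/validation split
#'
#' Selects `n_cal` calibration samples by greedy maximin Euclidean distance
#' on the (treated) spectra: the first two are the farthest pair, then each
#' step adds the sample maximizing its minimum distance to the selected
#' set. Ties break toward the lowest index, so duplicated rows never error.
#'
#' @param x Treated absorbance matrix or `nir_spectra`.
#' @param n_cal Number of calibration samples (default `floor(3n/4)`, the
#'   3:1 calibration:validation ratio).
#' @return A `sample_split`: calibration/validation index sets, the method
#'   tag and the calibration selection order.
#' @export
#' @examples
#' kennard_stone(matrix(c(0, 1, 4, 10)), n_cal = 3)
kennard_stone <- function(x, n_cal = NULL) {
  m <- .pre_matrix(x)
  n <- nrow(m)
  n_cal <- n_cal %||% floor(3 * n / 4)
  D <- as.matrix(stats::dist(m))
  .new_split(.greedy_maximin(D, n_cal), n, "KS")
}

#' SPXY calibration/validation split
#'
#' Kennard-Stone on the joint distance
#' `d(i,j) = d_X(i,j)/max(d_X) + d_y(i,j)/max(d_y)`, so the split spans
#' both the spectral and the analyte space. If all `y` are equal the
#' y-term is dropped and the result equals [kennard_stone()].
#'
#' @inheritParams kennard_stone
#' @param y Analyte vector (one value per sample).
#' @export
spxy <- function(x, y, n_cal = NULL) {
  m <- .pre_matrix(x)
  n <- nrow(m)
  if (length(y) != n) abort("`y` must have one value per sample.")
  if (anyNA(y) || any(!is.finite(y))) abort("`y` must be finite.")
  n_cal <- n_cal %||% floor(3 * n / 4)
  Dx <- as.matrix(stats::dist(m))
  Dy <- as.matrix(stats::dist(matrix(y)))
  D <- Dx / max(Dx)
  if (max(Dy) > 0) D <- D + Dy / max(Dy)
  .new_split(.greedy_maximin(D, n_cal), n, "SPXY")
}

#' Split an aligned dataset 3:1
#'
#' Convenience wrapper choosing [kennard_stone()] or [spxy()] with the
#' default `floor(3n/4)` calibration size, which reproduces the published
#' subset sizes 98 -> 73/25, 61 -> 45/16 and 37 -> 27/10.
#'
#' @param x Treated spectra (matrix or `nir_spectra`).
#' @param method `"ks"` or `"spxy"`.
#' @param y Analyte vector, required for `"spxy"`.
#' @param ratio Calibration fraction (default 3/4).
#' @return A `sample_split`.
#' @export
split_samples <- function(x, method = c("spxy", "ks"), y = NULL, ratio = 3 / 4) {
  method <- match.arg(method)
  n <- nrow(.pre_matrix(x))
  n_cal <- floor(ratio * n)
  if (method == "ks") {
    kennard_stone(x, n_cal)
  } else {
    if (is.null(y)) abort("SPXY needs the analyte vector `y`.")
    spxy(x, y, n_cal)
  }
}

#' @exportS3Method
tidy.sample_split <- function(x, ...) {
  n <- length(x$calibration) + length(x$validation)
  tibble::tibble(
    index = seq_len(n),
    subset = ifelse(seq_len(n) %in% x$calibration, "calibration", "validation"),
    selection_rank = match(seq_len(n), x$order)
  )
}
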