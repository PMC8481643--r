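# Spectral pretreatments: scatter correction (MSC / SNV), Savitzky-Golay
# smoothing and derivatives, and their composition into recipes. All
# operators accept either a bare absorbance matrix or a `nir_spectra` tibble
# and return the same kind of object.

.pre_matrix <- function(x) {
  if (is.matrix(x)) x else spectra_matrix(x)
}

.pre_restore <- function(x, m, attrs = NULL) {
  out <- if (is.matrix(x)) m else set_spectra_matrix(x, m)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  out
}

.row_label <- function(m, i) {
  rownames(m)[i] %||% as.character(i)
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed by ordinary least squares on a reference
#' spectrum, `x_i ~ a_i + b_i * ref`, and corrected as `(x_i - a_i) / b_i`.
#' The reference defaults to the column mean of `x`; pass the calibration
#' reference (attribute `msc_reference` of a corrected calibration set) to
#' correct validation spectra against the calibration mean.
#'
#' @param x Absorbance matrix (samples x wavelengths) or `nir_spectra`.
#' @param reference Optional reference spectrum (numeric vector).
#' @return Corrected object of the same kind, with attributes
#'   `msc_reference`, `msc_a` (offsets) and `msc_b` (slopes).
#' @export
msc <- function(x, reference = NULL) {
  m <- .pre_matrix(x)
  if (is.null(reference)) {
    if (nrow(m) < 2L) abort("MSC needs >= 2 samples when `reference` is omitted.")
    reference <- colMeans(m)
  }
  if (length(reference) != ncol(m)) {
    abort("`reference` length must equal the number of wavelengths.")
  }
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom < 1e-24) abort("MSC reference spectrum is constant.")
  mc <- m - rowMeans(m)            # row-centered
  b <- as.vector(mc %*% rc) / denom
  a <- rowMeans(m) - b * mean(reference)
  bad <- which(abs(b) < 1e-12)
  if (length(bad)) {
    abort(paste0("MSC slope numerically zero for sample(s): ",
                 paste(vapply(bad, function(i) .row_label(m, i), ""),
                       collapse = ", ")))
  }
  corrected <- (m - a) / b
  .pre_restore(x, corrected,
               list(msc_reference = as.numeric(reference), msc_a = a, msc_b = b))
}

#' Standard normal variate transformation
#'
#' Each spectrum is independently centered to mean zero and scaled to unit
#' standard deviation (n-1 denominator).
#'
#' @inheritParams msc
#' @return Corrected object of the same kind.
#' @export
snv <- function(x) {
  m <- .pre_matrix(x)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  bad <- which(s < 1e-24)
  if (length(bad)) {
    abort(paste0("SNV undefined for constant spectrum in sample(s): ",
                 paste(vapply(bad, function(i) .row_label(m, i), ""),
                       collapse = ", ")))
  }
  .pre_restore(x, (m - mu) / s)
}

# Dense Savitzky-Golay operator (p x p). Interior rows are the classic
# least-squares convolution weights; the first/last half-windows evaluate
# the terminal polynomial fits so output length equals input length.
# Cached: the pipeline reuses a handful of (p, window, poly, deriv) combos.
.savgol_cache <- new.env(parent = emptyenv())

.savgol_operator <- function(p, window, polyorder, derivative) {
  key <- paste(p, window, polyorder, derivative, sep = "_")
  hit <- .savgol_cache[[key]]
  if (!is.null(hit)) return(hit)
  op <- .savgol_operator_build(p, window, polyorder, derivative)
  .savgol_cache[[key]] <- op
  op
}

.savgol_operator_build <- function(p, window, polyorder, derivative) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, "^")
  pinv <- solve(crossprod(A), t(A))   # (poly+1) x window
  eval_row <- function(t) {
    k <- 0:polyorder
    coef <- ifelse(k >= derivative,
                   factorial(k) / factorial(pmax(k - derivative, 0)) *
                     t^(k - derivative),
                   0)
    # 0^0 care: t = 0 and k = derivative -> coefficient factorial(d)
    if (t == 0) {
      coef <- numeric(polyorder + 1)
      if (derivative <= polyorder) coef[derivative + 1] <- factorial(derivative)
    }
    as.numeric(coef %*% pinv)
  }
  centre <- eval_row(0)
  op <- matrix(0, p, p)
  for (j in seq_len(p)) {
    if (j <= h) {
      op[j, 1:window] <- eval_row(j - h - 1L)
    } else if (j > p - h) {
      op[j, (p - window + 1L):p] <- eval_row(j - (p - h))
    } else {
      op[j, (j - h):(j + h)] <- centre
    }
  }
  op
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Per-spectrum local polynomial filtering. Derivatives are per index step
#' on the wavenumber grid (not per cm^-1), which rescales coefficients but
#' not model quality on an even grid.
#'
#' @inheritParams msc
#' @param window Odd window length in points, `> polyorder`.
#' @param polyorder Local polynomial degree.
#' @param derivative Derivative order (0 = smoothing only), `<= polyorder`.
#' @return Treated object of the same kind (same dimensions as the input).
#' @export
savgol <- function(x, window = 51L, polyorder = 2L, derivative = 0L) {
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  derivative <- as.integer(derivative)
  if (window %% 2L == 0L) abort("`window` must be odd.")
  if (window <= polyorder) abort("`window` must exceed `polyorder`.")
  if (derivative > polyorder) abort("`derivative` must be <= `polyorder`.")
  if (derivative < 0L || polyorder < 0L) abort("Orders must be >= 0.")
  m <- .pre_matrix(x)
  if (ncol(m) < window) abort("Fewer wavelengths than the filter window.")
  op <- .savgol_operator(ncol(m), window, polyorder, derivative)
  .pre_restore(x, m %*% t(op))
}

#' Norris gap-segment derivative (optional alternative)
#'
#' Segment-averaged finite differences across a gap: first derivative
#' `(s[j+g] - s[j-g]) / (2g)`, second `(s[j+g] - 2 s[j] + s[j-g]) / g^2`,
#' where `s` is the `segment`-point moving average. Offered because some
#' commercial NIR software labels its derivative "Norris"; the package
#' default is [savgol()]. Edges are padded by replicating terminal values.
#'
#' @inheritParams msc
#' @param segment Odd segment length for the moving average.
#' @param gap Gap size `g` in points.
#' @param derivative 1 or 2.
#' @return Treated object of the same kind.
#' @export
norris_gap <- function(x, segment = 5L, gap = 5L, derivative = 1L) {
  segment <- as.integer(segment); gap <- as.integer(gap)
  if (segment %% 2L == 0L) abort("`segment` must be odd.")
  if (!derivative %in% 1:2) abort("`derivative` must be 1 or 2.")
  m <- .pre_matrix(x)
  p <- ncol(m)
  if (p < segment + 2L * gap) abort("Spectrum too short for segment/gap.")
  half <- (segment - 1L) %/% 2L
  pad_idx <- function(i) pmin(pmax(i, 1L), p)
  smooth <- vapply(seq_len(p), function(j) {
    rowMeans(m[, pad_idx((j - half):(j + half)), drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(smooth))) smooth <- matrix(smooth, nrow = nrow(m))
  d <- matrix(0, nrow(m), p, dimnames = dimnames(m))
  for (j in seq_len(p)) {
    lo <- pad_idx(j - gap); hi <- pad_idx(j + gap)
    d[, j] <- if (derivative == 1L) {
      (smooth[, hi] - smooth[, lo]) / (2 * gap)
    } else {
      (smooth[, hi] - 2 * smooth[, j] + smooth[, lo]) / gap^2
    }
  }
  .pre_restore(x, d)
}

#' Define a preprocessing recipe
#'
#' A recipe is scatter correction followed by Savitzky-Golay
#' smoothing/derivative, in that order. Mean-centering is not part of the
#' recipe; it happens inside model fitting.
#'
#' @param scatter One of `"msc"`, `"snv"`, `"none"`.
#' @param window,polyorder,derivative Savitzky-Golay settings; see
#'   [savgol()]. The shipped default (51, 2, 2) is the nearest odd symmetric
#'   window to the nominal "52 smoothing points" of the source treatments.
#' @return A `preprocess_recipe` object.
#' @export
#' @examples
#' preprocess_recipe("msc", 51, 2, 2)
#' parse_recipe("SNV+SG51p2d1")
preprocess_recipe <- function(scatter = c("msc", "snv", "none"),
                              window = 51L, polyorder = 2L, derivative = 2L) {
  scatter <- match.arg(tolower(scatter[1]), c("msc", "snv", "none"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  derivative <- as.integer(derivative)
  if (window %% 2L == 0L || window <= polyorder) {
    abort("`window` must be odd and greater than `polyorder`.")
  }
  if (!derivative %in% 0:2 || derivative > polyorder) {
    abort("`derivative` must be in 0..2 and <= `polyorder`.")
  }
  structure(
    list(scatter = scatter, window = window, polyorder = polyorder,
         derivative = derivative),
    class = "preprocess_recipe"
  )
}

#' @export
format.preprocess_recipe <- function(x, ...) {
  sprintf("%s+SG%dp%dd%d", toupper(x$scatter), x$window, x$polyorder,
          x$derivative)
}

#' @export
print.preprocess_recipe <- function(x, ...) {
  cat("<preprocess_recipe>", format(x), "\n")
  invisible(x)
}

#' Parse a recipe string
#'
#' Strings use the treatment vocabulary `"MSC+SG51p2d2"`,
#' `"SNV+SG51p2d1"`, `"NONE+SG51p2d0"`.
#'
#' @param text A recipe string.
#' @return A `preprocess_recipe` object.
#' @export
parse_recipe <- function(text) {
  m <- regmatches(text,
    regexec("^(MSC|SNV|NONE)\\+SG(\\d+)P(\\d+)D(\\d+)$", toupper(text)))[[1]]
  if (length(m) == 0L) {
    abort(paste0("Cannot parse recipe string: ", text,
                 " (expected e.g. 'MSC+SG51p2d2')."))
  }
  preprocess_recipe(tolower(m[2]), as.integer(m[3]), as.integer(m[4]),
                    as.integer(m[5]))
}

#' Apply a preprocessing recipe
#'
#' Applies scatter correction, then Savitzky-Golay smoothing/derivative.
#' The returned state carries the MSC reference (and nothing else) so the
#' identical transform can be applied to validation spectra with
#' `apply_recipe(x_val, recipe, state = out$state)`.
#'
#' @param x Absorbance matrix or `nir_spectra`.
#' @param recipe A [preprocess_recipe()] (or recipe string).
#' @param state Optional fitted state from a previous calibration call.
#' @return List with `treated` (same kind as `x`) and `state`.
#' @export
apply_recipe <- function(x, recipe, state = NULL) {
  if (is.character(recipe)) recipe <- parse_recipe(recipe)
  stopifnot(inherits(recipe, "preprocess_recipe"))
  out_state <- list(msc_reference = NULL)
  y <- switch(recipe$scatter,
    msc = {
      ref <- state$msc_reference
      corrected <- msc(x, reference = ref)
      out_state$msc_reference <- attr(corrected, "msc_reference")
      corrected
    },
    snv = snv(x),
    none = x
  )
  treated <- savgol(y, recipe$window, recipe$polyorder, recipe$derivative)
  list(treated = treated, state = out_state)
}
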