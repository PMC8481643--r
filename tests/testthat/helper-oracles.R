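# Independent brute-force oracles and small fixtures, built in code.

# Naive Kennard-Stone: explicit loops, no shared code with the package's
# greedy implementation beyond base R.
brute_maximin <- function(D, n_cal) {
  n <- nrow(D)
  best_i <- 1L; best_j <- 2L; best_d <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > best_d) { best_i <- i; best_j <- j; best_d <- D[i, j] }
  }
  sel <- c(best_i, best_j)
  while (length(sel) < n_cal) {
    cand <- setdiff(1:n, sel)
    best_c <- cand[1]; best_m <- -Inf
    for (c in cand) {
      m <- Inf
      for (s in sel) m <- min(m, D[c, s])
      if (m > best_m) { best_m <- m; best_c <- c }
    }
    sel <- c(sel, best_c)
  }
  sel
}

brute_ks <- function(X, n_cal) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  brute_maximin(D, n_cal)
}

brute_spxy <- function(X, y, n_cal) {
  n <- nrow(X)
  Dx <- matrix(0, n, n); Dy <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    Dy[i, j] <- abs(y[i] - y[j])
  }
  D <- Dx / max(Dx)
  if (max(Dy) > 0) D <- D + Dy / max(Dy)
  brute_maximin(D, n_cal)
}

# Reduced-wavelength simulated study: full pipeline semantics at a fraction
# of the cost (the 1,557-point grid is only needed for scale checks).
small_study <- function(seed = 11L, p = 180L, n_hulled = 31L,
                        n_hull_less = 19L, effects = effect_model()) {
  simulate_study(study_config(
    n_hulled = n_hulled, n_hull_less = n_hull_less,
    effects = effects, wn = default_grid(p), seed = seed
  ))
}

# Tiny deterministic spectra fixture.
toy_spectra <- function(n = 4L, p = 6L, seed = 1L) {
  withr::with_seed(seed, {
    nir_spectra(matrix(runif(n * p), n, p),
                seq(4000, 10000, length.out = p),
                sprintf("T%02d", seq_len(n)))
  })
}
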