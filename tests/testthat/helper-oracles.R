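# Independent small-scale oracles used across the test files.

# Direct double-loop cross-correlation (the estimator's reference).
direct_crosscorr <- function(a, b, n_lags, estimator = "unbiased") {
  M <- length(a)
  vapply(0:n_lags, function(n) {
    s <- sum(a[seq_len(M - n)] * b[seq_len(M - n) + n])
    s / if (estimator == "unbiased") (M - n) else M
  }, numeric(1L))
}

# Stationary correlations of the harmonic-well GLE from the linear
# embedding: state (x, v, z_1..z_n) with z_i = y_i - x obeys a linear SDE
# whose lagged covariance is exp(A t) Sigma.  Returns the requested matrix
# element as a function of lag time.
embedding_corr <- function(K, gammas, taus, mass, kT) {
  nz <- length(gammas)
  ks <- gammas / taus
  A <- matrix(0, 2 + nz, 2 + nz)
  A[1, 2] <- 1
  A[2, 1] <- -K / mass
  A[2, 2 + seq_len(nz)] <- ks / mass
  for (i in seq_len(nz)) {
    A[2 + i, 2 + i] <- -1 / taus[i]
    A[2 + i, 2] <- -1
  }
  Sig <- diag(c(kT / K, kT / mass, kT / ks), nrow = 2 + nz)
  ee <- eigen(A)
  V <- ee$vectors
  Vi <- solve(V)
  function(t, i = 2L, j = 2L)
    vapply(t, function(tt)
      Re(V %*% diag(exp(ee$values * tt), nrow = nrow(A)) %*% Vi %*% Sig)[i, j],
      numeric(1L))
}

# Overdamped mean first-passage time a -> b by the standard double
# integral tau = (1/D) int_a^b dy exp(U/kT) int_{lo}^{y} dz exp(-U/kT),
# evaluated by cumulative trapezoids on a fine grid.
quadrature_mfpt <- function(ufun, kT, gamma_tot, a, b, lo = NULL, n = 20001L) {
  D <- kT / gamma_tot
  if (is.null(lo)) lo <- a - 5 * abs(b - a)
  grid <- seq(lo, b, length.out = n)
  h <- grid[2L] - grid[1L]
  w <- exp(-ufun(grid) / kT)
  inner <- (cumsum(w) - w / 2 - w[1L] / 2) * h     # int_lo^y exp(-U/kT)
  integrand <- exp(ufun(grid) / kT) * inner
  sel <- grid >= a
  sum((integrand[sel][-1L] + integrand[sel][-sum(sel)]) / 2) * h / D
}

# Shared benchmark systems (kept deliberately small where used in tests).
benchmark_system <- function() {
  list(kernel = memory_kernel(c(150, 350), c(2, 12)),
       pmf = pmf_polynomial(double_well_coefs(0.32, 0.66, 1.0, 3 * 2.494),
                            kT = 2.494, support = c(0.1, 1.25)),
       mass = 1250, kT = 2.494, dt_sim = 0.18)
}
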