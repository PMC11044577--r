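# Internal Gaussian-process regression with a Matern-5/2 kernel plus a
# fitted white-noise term.  Inputs are expected scaled to the unit box and
# outputs standardized by the caller.  Hyperparameters (length scale,
# signal variance, noise variance) are chosen by maximizing the marginal
# likelihood with multi-start L-BFGS-B; fully deterministic.

matern52 <- function(r, ell) {
  z <- sqrt(5) * r / ell
  (1 + z + z^2 / 3) * exp(-z)
}

gp_nll <- function(logpar, D, y) {
  ell <- exp(logpar[1L]); sf2 <- exp(logpar[2L]); sn2 <- exp(logpar[3L])
  n <- length(y)
  K <- sf2 * matern52(D, ell) + diag(sn2 + 1e-10, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}

gp_fit <- function(X, y) {
  X <- as.matrix(X)
  D <- as.matrix(dist(X))
  starts <- list(c(log(0.3), 0, log(1e-2)),
                 c(log(1.0), 0, log(1e-4)),
                 c(log(0.1), 0, log(1e-1)))
  lower <- c(log(0.01), -8, log(1e-8))
  upper <- c(log(10), 8, log(4))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, gp_nll, method = "L-BFGS-B", lower = lower, upper = upper,
            D = D, y = y, control = list(maxit = 200L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  ell <- exp(best$par[1L]); sf2 <- exp(best$par[2L]); sn2 <- exp(best$par[3L])
  K <- sf2 * matern52(D, ell) + diag(sn2 + 1e-10, length(y))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  list(X = X, y = y, ell = ell, sf2 = sf2, sn2 = sn2, L = L, alpha = alpha)
}

gp_predict <- function(gp, Xnew) {
  Xnew <- matrix(Xnew, ncol = ncol(gp$X))
  # cross-distances
  n <- nrow(gp$X); m <- nrow(Xnew)
  D2 <- outer(rowSums(Xnew^2), rep(1, n)) +
    outer(rep(1, m), rowSums(gp$X^2)) - 2 * Xnew %*% t(gp$X)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  Ks <- gp$sf2 * matern52(D, gp$ell)
  mu <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  s2 <- pmax(gp$sf2 - colSums(v^2), 1e-12)
  list(mean = mu, sd = sqrt(s2))
}

# Expected improvement (minimization) at points Xnew given incumbent best
# posterior-mean value y_best.
gp_ei <- function(gp, Xnew, y_best) {
  p <- gp_predict(gp, Xnew)
  z <- (y_best - p$mean) / p$sd
  (y_best - p$mean) * pnorm(z) + p$sd * dnorm(z)
}
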