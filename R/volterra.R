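#' Running kernel integral by Volterra inversion
#'
#' Solves the Volterra equation of the first kind obtained by integrating
#' the velocity-multiplied GLE over time and inserting the equilibrium
#' identity \eqn{m C^{vv}(0) = C^{\nabla U x}(0)}:
#' \deqn{\int_0^t G(s)\, C^{vv}(t-s)\, ds = C^{\nabla U x}(t) - m C^{vv}(t)}
#' for the running kernel integral \eqn{G(t) = \int_0^t \Gamma(s) ds}.  The
#' convolution is discretized by the trapezoidal rule and solved lag by lag
#' through forward substitution with \eqn{G(0) = 0}:
#' \deqn{G_n = \Big[\mathrm{rhs}_n/\Delta t - \tfrac12 G_0 C^{vv}_n -
#'   \sum_{j=1}^{n-1} G_j C^{vv}_{n-j}\Big] / \big(\tfrac12 C^{vv}_0\big).}
#' This route is preferred over differentiating the unintegrated equation,
#' which is numerically unstable.
#'
#' Before inverting, the identity \eqn{m C^{vv}(0) = C^{\nabla U x}(0)} is
#' checked: a relative mismatch beyond `identity_tol` indicates either a
#' unit/sign error or (at coarse sampling intervals) attenuation of the
#' discretized velocities, and triggers a warning (or an error when
#' `on_identity_fail = "error"`).  A sign flip between the two always
#' errors.
#'
#' The equilibrium identity is not only checked but, by default, inserted:
#' with `mass_mode = "equipartition"` the mass entering the right-hand side
#' is the effective mass implied by the data,
#' \eqn{m_{eff} = C^{\nabla U x}(0)/C^{vv}(0)} (equipartition,
#' \eqn{m = k_B T/\langle v^2 \rangle} up to the PMF normalization), which
#' makes the right-hand side vanish exactly at t = 0 and renders the
#' forward substitution insensitive to the attenuation of discretized
#' velocities.  `mass_mode = "given"` uses the supplied mass unchanged.
#'
#' @param corr a [correlation_set()].
#' @param mass effective mass of the coordinate in u (stored; used in the
#'   inversion only when `mass_mode = "given"`).
#' @param mass_mode `"equipartition"` (default) or `"given"`, see Details.
#' @param identity_tol relative tolerance of the t = 0 consistency check
#'   between `mass` and the equipartition mass (default 0.2).
#' @param on_identity_fail `"warn"` (default), `"error"`, or `"none"`.
#' @return an object of class `"extraction_result"` with `G` (u/ps) filled
#'   and `Gamma` unset; see [differentiate_G()].
#' @export
solve_G <- function(corr, mass, mass_mode = c("equipartition", "given"),
                    identity_tol = 0.2,
                    on_identity_fail = c("warn", "error", "none")) {
  on_identity_fail <- match.arg(on_identity_fail)
  mass_mode <- match.arg(mass_mode)
  stopifnot(inherits(corr, "correlation_set"), mass > 0)
  cvv <- corr$cvv
  if (cvv[1L] <= 0) stop("cvv[0] must be positive")
  m_cvv0 <- mass * cvv[1L]
  cux0 <- corr$cgradUx[1L]
  if (cux0 * m_cvv0 <= 0)
    stop("sign mismatch between m*cvv[0] and cgradUx[0]; ",
         "check the potential gradient sign and units")
  mismatch <- abs(m_cvv0 - cux0) / abs(cux0)
  if (mismatch > identity_tol && on_identity_fail != "none") {
    msg <- sprintf(paste0("equilibrium identity m*cvv[0] = cgradUx[0] violated by %.1f%%; ",
                          "expected at coarse sampling intervals (velocity attenuation), ",
                          "otherwise check units"), 100 * mismatch)
    if (on_identity_fail == "error") stop(msg) else warning(msg)
  }
  m_used <- if (mass_mode == "equipartition") cux0 / cvv[1L] else mass
  n <- corr$n_lags
  dt <- corr$dt
  rhs <- corr$cgradUx - m_used * cvv
  G <- numeric(n + 1L)  # G[1] = G(0) = 0
  diag_term <- 0.5 * cvv[1L]
  if (abs(diag_term) < 1e-14 * max(abs(cvv)))
    stop("ill-conditioned inversion: diagonal term ~ 0")
  for (k in seq_len(n)) {
    # trapezoid over s grid 0..k: (dt) * [ 1/2 G_0 cvv_k + sum_{j=1}^{k-1} G_j cvv_{k-j} + 1/2 G_k cvv_0 ]
    acc <- 0
    if (k >= 2L)
      acc <- sum(G[2:k] * cvv[k:2])
    G[k + 1L] <- (rhs[k + 1L] / dt - acc) / diag_term
  }
  structure(list(dt = dt, G = G, Gamma = NULL, mass = mass,
                 mass_used = m_used,
                 scheme = list(quadrature = "trapezoid",
                               mass_mode = mass_mode,
                               identity_mismatch = mismatch,
                               estimator = corr$estimator),
                 n_lags = n),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(sprintf("extraction_result: %d lags, dt = %g ps, G(t_max) = %.5g u/ps%s\n",
              x$n_lags, x$dt, x$G[length(x$G)],
              if (is.null(x$Gamma)) "" else ", Gamma filled"))
  invisible(x)
}

#' Memory kernel by numerical differentiation of G
#'
#' \eqn{\Gamma(t) = dG/dt} via central differences in the interior and
#' one-sided differences at both ends; the scheme is recorded in the
#' result so alternative discretizations remain auditable.
#'
#' @param res an `"extraction_result"` from [solve_G()] (>= 3 lags).
#' @return the input with `Gamma` (u/ps^2) filled.
#' @export
differentiate_G <- function(res) {
  stopifnot(inherits(res, "extraction_result"))
  G <- res$G
  n <- length(G)
  if (n < 3L) stop("need at least 3 points to differentiate G")
  dt <- res$dt
  Gamma <- numeric(n)
  Gamma[1L] <- (G[2L] - G[1L]) / dt
  Gamma[n] <- (G[n] - G[n - 1L]) / dt
  Gamma[2:(n - 1L)] <- (G[3:n] - G[1:(n - 2L)]) / (2 * dt)
  res$Gamma <- Gamma
  res$scheme$derivative <- "central interior, one-sided ends"
  res
}

#' Serialize an extraction result as TSV
#'
#' Columns: `lag_ps, G_u_per_ps, Gamma_u_per_ps2` (Gamma column NA when not
#' yet differentiated).
#'
#' @param res an `"extraction_result"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_extraction <- function(res, path) {
  stopifnot(inherits(res, "extraction_result"))
  con <- file(path, "w")
  writeLines(sprintf("# memkernel extraction  dt_ps=%.10g  mass_u=%.10g  quadrature=%s",
                     res$dt, res$mass, res$scheme$quadrature), con)
  writeLines("# lag_ps\tG_u_per_ps\tGamma_u_per_ps2", con)
  g2 <- if (is.null(res$Gamma)) rep(NA_real_, length(res$G)) else res$Gamma
  tab <- data.frame(lag = (seq_along(res$G) - 1) * res$dt, G = res$G, Gamma = g2)
  write.table(format(tab, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
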