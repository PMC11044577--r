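# Ascending-coefficient polynomial helpers (coefs[1] + coefs[2]*x + ...)
polyval_asc <- function(coefs, x) {
  r <- rep(0, length(x))
  for (i in rev(seq_along(coefs))) r <- r * x + coefs[i]
  r
}

polyder_asc <- function(coefs) {
  n <- length(coefs)
  if (n <= 1L) return(0)
  coefs[-1L] * seq_len(n - 1L)
}

#' Potential of mean force from an equilibrium histogram
#'
#' Boltzmann inversion: the stationary density rho(x) is estimated from a
#' normalized histogram and the free-energy profile is
#' \eqn{U(x) = -k_B T \ln \rho(x)}, shifted so its minimum is zero.  A cubic
#' smoothing spline through the (bin center, U) pairs provides a smooth
#' \eqn{U(x)} and \eqn{\nabla U(x)} between the outermost nonempty bin
#' centers; beyond them the profile is extended quadratically (harmonic
#' walls matching the boundary value and slope), which keeps GLE
#' simulations confined without ad-hoc reflecting boundaries.
#'
#' Interior empty bins are refused (interpolating across unvisited regions
#' would fabricate barrier shapes); lower `n_bins` instead.
#'
#' @param traj a [trajectory()]; always use the full-resolution data here,
#'   even when correlation functions are later computed from subsampled
#'   data (the default policy of the package).
#' @param kT thermal energy in kJ/mol.
#' @param n_bins number of histogram bins (>= 5), default 100.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` selects it by generalized
#'   cross-validation.
#' @return an object of class `"pmf"`.
#' @export
estimate_pmf <- function(traj, kT, n_bins = 100, spar = NULL) {
  stopifnot(inherits(traj, "trajectory"), kT > 0)
  if (n_bins < 5) stop("n_bins must be >= 5")
  x <- traj$positions
  edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  nonempty <- which(counts > 0L)
  if (any(diff(nonempty) > 1L)) {
    # Isolated outliers produce sparse bins separated by gaps near the
    # edges of the sampled range.  Keep the central contiguous run (the
    # one containing the modal bin) if the discarded bins hold at most
    # 0.1% of the samples; a gap through well-sampled territory is a
    # genuine unvisited region and is refused.
    runs <- split(nonempty, cumsum(c(1L, diff(nonempty) > 1L)))
    main <- runs[[which.max(vapply(runs, function(r) max(counts[r]), numeric(1L)))]]
    dropped <- sum(counts[setdiff(nonempty, main)])
    if (dropped > 0.001 * length(x))
      stop("interior empty bin in the histogram; lower n_bins ",
           "(refusing to interpolate across unvisited regions)")
    nonempty <- main
  }
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  bw <- diff(edges)[1L]
  rho <- counts[nonempty] / (length(x) * bw)
  u <- -kT * log(rho)
  u <- u - min(u)
  cc <- centers[nonempty]
  fit <- if (is.null(spar)) smooth.spline(cc, u) else smooth.spline(cc, u, spar = spar)
  support <- range(cc)
  # Harmonic walls: match boundary value and slope; wall curvature taken
  # from the spline curvature at the boundary, floored at a confining
  # minimum of 200*kT/width^2 (turning distance ~ width/10).
  width <- diff(support)
  k_floor <- 200 * kT / width^2
  d1 <- predict(fit, support, deriv = 1)$y
  d2 <- predict(fit, support, deriv = 2)$y
  wall_k <- pmax(d2, k_floor)
  obj <- structure(list(kind = "spline", kT = kT,
                        bin_edges = edges, centers = cc, u_values = u,
                        spline = fit, support = support,
                        boundary_value = predict(fit, support)$y,
                        boundary_slope = d1, wall_k = wall_k,
                        spline_smoothing = list(spar = fit$spar,
                                                lambda = fit$lambda),
                        meta = list(n_bins = n_bins,
                                    n_samples = length(x))),
                   class = "pmf")
  obj
}

#' Analytic polynomial potential
#'
#' Wraps a confining polynomial \eqn{U(x)} (ascending coefficients, kJ/mol,
#' positive leading even coefficient) as a `"pmf"` object with exact
#' gradient, used for synthetic ground-truth systems.
#'
#' @param coefs ascending polynomial coefficients of U(x) in kJ/mol.
#' @param kT thermal energy in kJ/mol (stored for serialization and
#'   Boltzmann sampling).
#' @param support nm range over which the potential is considered sampled
#'   (used for plotting/sampling grids only; the polynomial is global).
#' @return an object of class `"pmf"`.
#' @export
pmf_polynomial <- function(coefs, kT, support = c(0, 1.3)) {
  coefs <- as.numeric(coefs)
  n <- length(coefs)
  if (n < 3L || coefs[n] <= 0 || (n - 1L) %% 2L != 0L)
    stop("polynomial must be confining: even degree, positive leading coefficient")
  structure(list(kind = "poly", kT = kT, coefs = coefs,
                 grad_coefs = polyder_asc(coefs),
                 support = sort(as.numeric(support)),
                 meta = list()),
            class = "pmf")
}

#' @export
print.pmf <- function(x, ...) {
  if (x$kind == "poly")
    cat(sprintf("pmf (analytic polynomial, degree %d), support [%.3g, %.3g] nm\n",
                length(x$coefs) - 1L, x$support[1L], x$support[2L]))
  else
    cat(sprintf("pmf (histogram + smoothing spline, %d bins), support [%.3g, %.3g] nm\n",
                x$meta$n_bins, x$support[1L], x$support[2L]))
  invisible(x)
}

#' Evaluate the potential of mean force
#'
#' @param pmf a `"pmf"` object.
#' @param x positions in nm.
#' @return U(x) in kJ/mol (minimum-shifted for histogram PMFs).
#' @export
pmf_value <- function(pmf, x) {
  stopifnot(inherits(pmf, "pmf"))
  if (pmf$kind == "poly") return(polyval_asc(pmf$coefs, x))
  lo <- pmf$support[1L]; hi <- pmf$support[2L]
  u <- rep(NA_real_, length(x))
  ins <- x >= lo & x <= hi
  if (any(ins)) u[ins] <- predict(pmf$spline, x[ins])$y
  left <- x < lo
  if (any(left)) {
    d <- x[left] - lo
    u[left] <- pmf$boundary_value[1L] + pmf$boundary_slope[1L] * d +
      0.5 * pmf$wall_k[1L] * d^2
  }
  right <- x > hi
  if (any(right)) {
    d <- x[right] - hi
    u[right] <- pmf$boundary_value[2L] + pmf$boundary_slope[2L] * d +
      0.5 * pmf$wall_k[2L] * d^2
  }
  u
}

#' Evaluate the potential gradient
#'
#' @param pmf a `"pmf"` object.
#' @param x positions in nm.
#' @return dU/dx in kJ/mol/nm; continuous across the harmonic-wall
#'   boundaries of histogram PMFs.
#' @export
pmf_gradient <- function(pmf, x) {
  stopifnot(inherits(pmf, "pmf"))
  if (pmf$kind == "poly") return(polyval_asc(pmf$grad_coefs, x))
  lo <- pmf$support[1L]; hi <- pmf$support[2L]
  g <- rep(NA_real_, length(x))
  ins <- x >= lo & x <= hi
  if (any(ins)) g[ins] <- predict(pmf$spline, x[ins], deriv = 1)$y
  left <- x < lo
  if (any(left)) g[left] <- pmf$boundary_slope[1L] + pmf$wall_k[1L] * (x[left] - lo)
  right <- x > hi
  if (any(right)) g[right] <- pmf$boundary_slope[2L] + pmf$wall_k[2L] * (x[right] - hi)
  g
}

#' Potential-gradient series along a trajectory
#'
#' Evaluates \eqn{\nabla U} at every trajectory position; used to build the
#' gradient-velocity and gradient-position correlation functions of the
#' Volterra inversion.
#'
#' @param pmf a `"pmf"` object.
#' @param traj a [trajectory()].
#' @return numeric vector in kJ/mol/nm, one value per frame.
#' @export
grad_u_series <- function(pmf, traj) {
  stopifnot(inherits(traj, "trajectory"))
  pmf_gradient(pmf, traj$positions)
}

# Uniform gradient lookup table for the compiled integrator.  The table
# range extends past the sampled support so that the harmonic-wall region is
# tabulated; the integrator continues the end slope linearly, i.e. the same
# wall.
pmf_gradient_table <- function(pmf, n_grid = 4001L, pad_frac = 0.25) {
  w <- diff(pmf$support)
  lo <- pmf$support[1L] - pad_frac * w
  hi <- pmf$support[2L] + pad_frac * w
  xg <- seq(lo, hi, length.out = n_grid)
  list(x0 = lo, dx = xg[2L] - xg[1L], g = pmf_gradient(pmf, xg))
}

# Draw one position from the Boltzmann weight exp(-U/kT) on a fine grid.
sample_boltzmann <- function(pmf, kT, n_grid = 4001L) {
  xg <- seq(pmf$support[1L], pmf$support[2L], length.out = n_grid)
  u <- pmf_value(pmf, xg)
  w <- exp(-(u - min(u)) / kT)
  xg[sample.int(n_grid, 1L, prob = w)]
}

#' Serialize a PMF as TSV plus JSON sidecar
#'
#' Writes `(center, U, dU/dx)` on a uniform grid over the support and a
#' `.json` sidecar with kT, binning and smoothing metadata.
#'
#' @param pmf a `"pmf"` object.
#' @param path output TSV path (sidecar at `paste0(path, ".json")`).
#' @param n_grid number of grid points.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path, n_grid = 501L) {
  xg <- seq(pmf$support[1L], pmf$support[2L], length.out = n_grid)
  tab <- data.frame(x_nm = xg, u_kJ_mol = pmf_value(pmf, xg),
                    dudx_kJ_mol_nm = pmf_gradient(pmf, xg))
  con <- file(path, "w")
  writeLines("# memkernel pmf: x_nm\tu_kJ_mol\tdudx_kJ_mol_nm", con)
  write.table(format(tab, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  side <- list(kind = pmf$kind, kT = pmf$kT, support = pmf$support)
  if (pmf$kind == "spline") {
    side$n_bins <- pmf$meta$n_bins
    side$smoothing <- pmf$spline_smoothing
  } else side$coefs <- pmf$coefs
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
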