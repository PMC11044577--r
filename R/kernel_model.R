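#' Multiexponential memory kernel
#'
#' Parametrization
#' \deqn{\Gamma(t) = \sum_i (\gamma_i/\tau_i)\, e^{-t/\tau_i}, \qquad
#'       G(t) = \sum_i \gamma_i (1 - e^{-t/\tau_i}),}
#' so that \eqn{G(\infty) = \gamma_{tot} = \sum_i \gamma_i}.  Components
#' are stored sorted by ascending memory time, which removes
#' label-switching ambiguity.
#'
#' @param gammas friction coefficients \eqn{\gamma_i} in u/ps, all > 0.
#' @param taus memory times \eqn{\tau_i} in ps, all > 0; same length.
#' @return an object of class `"memory_kernel"`.
#' @export
memory_kernel <- function(gammas, taus) {
  gammas <- as.numeric(gammas); taus <- as.numeric(taus)
  if (length(gammas) != length(taus) || length(gammas) < 1L)
    stop("gammas and taus must be non-empty and of equal length")
  if (any(taus <= 0)) stop("all memory times must be positive")
  if (any(gammas < 0)) stop("friction coefficients must be non-negative")
  ord <- order(taus)
  structure(list(gammas = gammas[ord], taus = taus[ord]),
            class = "memory_kernel")
}

#' @export
print.memory_kernel <- function(x, ...) {
  cat(sprintf("memory_kernel: %d exponential component(s), gamma_tot = %.5g u/ps, tau_mem = %.5g ps\n",
              length(x$gammas), gamma_tot(x), tau_mem(x)))
  for (i in seq_along(x$gammas))
    cat(sprintf("  %d: gamma = %.5g u/ps, tau = %.5g ps\n",
                i, x$gammas[i], x$taus[i]))
  invisible(x)
}

#' Evaluate the kernel Gamma(t)
#' @param kernel a [memory_kernel()].
#' @param t times in ps.
#' @return Gamma(t) in u/ps^2.
#' @export
kernel_gamma <- function(kernel, t) {
  stopifnot(inherits(kernel, "memory_kernel"))
  t <- as.numeric(t)
  rowSums(matrix(vapply(seq_along(kernel$gammas), function(i)
    kernel$gammas[i] / kernel$taus[i] * exp(-t / kernel$taus[i]),
    numeric(length(t))), nrow = length(t)))
}

#' Evaluate the running integral G(t)
#' @param kernel a [memory_kernel()].
#' @param t times in ps.
#' @return G(t) in u/ps.
#' @export
kernel_G <- function(kernel, t) {
  stopifnot(inherits(kernel, "memory_kernel"))
  t <- as.numeric(t)
  rowSums(matrix(vapply(seq_along(kernel$gammas), function(i)
    kernel$gammas[i] * (1 - exp(-t / kernel$taus[i])),
    numeric(length(t))), nrow = length(t)))
}

#' Total friction coefficient
#' @param kernel a [memory_kernel()].
#' @return \eqn{\gamma_{tot} = \sum_i \gamma_i} in u/ps.
#' @export
gamma_tot <- function(kernel) {
  stopifnot(inherits(kernel, "memory_kernel"))
  sum(kernel$gammas)
}

#' Memory time (first moment of the kernel)
#'
#' \deqn{\tau_{mem} = \frac{\int_0^\infty s\,\Gamma(s)\,ds}
#'                         {\int_0^\infty \Gamma(s)\,ds}
#'                  = \frac{\sum_i \gamma_i \tau_i}{\sum_i \gamma_i}}
#' (analytic evaluation of the first-moment integrals for a
#' multiexponential kernel).
#'
#' @param kernel a [memory_kernel()].
#' @return memory time in ps.
#' @export
tau_mem <- function(kernel) {
  stopifnot(inherits(kernel, "memory_kernel"))
  g <- gamma_tot(kernel)
  if (g == 0) stop("gamma_tot is zero")
  sum(kernel$gammas * kernel$taus) / g
}

#' Characteristic time scales and kinetic regime
#'
#' Computes the memory time \eqn{\tau_{mem}}, the diffusion time
#' \eqn{\tau_D = \gamma_{tot} L^2 / k_B T} (time for a free Brownian
#' particle to diffuse over the barrier distance L), and the inertial time
#' \eqn{\tau_m = m/\gamma_{tot}}.  The kinetic regime follows the
#' single-exponential heuristic with \eqn{\tau_{mem}} as the
#' characteristic time of a multiscale kernel: `"markovian"` when
#' \eqn{\tau_{mem} < \tau_D/100}, `"slowdown"` when
#' \eqn{\tau_{mem} > 10\,\tau_D}, `"speedup"` in between (barrier crossing
#' accelerated relative to the Markovian description).
#'
#' @param kernel a [memory_kernel()].
#' @param mass effective mass in u.
#' @param kT thermal energy in kJ/mol.
#' @param L barrier distance in nm (>= 0).
#' @return an object of class `"timescale_report"` with fields `tau_mem`,
#'   `tau_D`, `tau_m` (all ps), `regime`, and `L`.
#' @export
timescales <- function(kernel, mass, kT, L) {
  stopifnot(inherits(kernel, "memory_kernel"), kT > 0, L >= 0, mass > 0)
  g <- gamma_tot(kernel)
  if (g == 0) stop("gamma_tot is zero")
  tm <- tau_mem(kernel)
  tD <- g * L^2 / kT
  regime <- if (tm < tD / 100) "markovian"
  else if (tm > 10 * tD) "slowdown"
  else "speedup"
  structure(list(tau_mem = tm, tau_D = tD, tau_m = mass / g,
                 gamma_tot = g, regime = regime, L = L),
            class = "timescale_report")
}

#' @export
print.timescale_report <- function(x, ...) {
  cat(sprintf(paste0("timescales: tau_mem = %.4g ps, tau_D = %.4g ps, ",
                     "tau_m = %.4g ps (%.3g fs)\n  gamma_tot = %.4g u/ps, ",
                     "L = %.3g nm, regime = %s\n"),
              x$tau_mem, x$tau_D, x$tau_m, 1000 * x$tau_m,
              x$gamma_tot, x$L, x$regime))
  invisible(x)
}

#' Fit a multiexponential kernel to an extraction result
#'
#' Least-squares fit of the parametrization of [memory_kernel()] to the
#' extracted \eqn{\Gamma(t)} and its running integral \eqn{G(t)}, with
#' combined loss
#' \deqn{L = \mathrm{MSE}(\Gamma)/\max(\Gamma_{data})^2 +
#'       \alpha_{mem}\, \mathrm{MSE}(G)/\max(G_{data})^2,}
#' i.e. both terms normalized by the squared maximum of their data series
#' so that \eqn{\alpha_{mem}} is O(1) and scale-free.  The minimization
#' runs in \eqn{\log_{10}(\gamma_i), \log_{10}(\tau_i)} space (the
#' components of realistic kernels span many decades) with a
#' differential-evolution global search followed by an L-BFGS-B polish;
#' both stages are deterministic given `seed`.
#'
#' Lags with \eqn{t < t_{min}} are excluded, which discards the sub-ps
#' oscillations of fine-resolution kernels that the exponential model
#' cannot and need not represent.
#'
#' The trapezoidal forward substitution of [solve_G()] supports a
#' marginally stable alternating mode, so extracted `G` series can carry
#' an even-odd oscillation around the true curve.  With
#' `smooth_G = TRUE` (default) the fit therefore uses the two-point
#' average \eqn{(G_j + G_{j+1})/2}, evaluated on the half-lag grid
#' \eqn{(j + 1/2)\Delta t} where it is second-order accurate, which
#' annihilates the alternating mode exactly; \eqn{\Gamma} from
#' [differentiate_G()] is already alternation-free (central differences
#' span two lags).
#'
#' @param res an `"extraction_result"` with both `G` and `Gamma` filled.
#' @param n_exp number of exponential components (1-8, default 5).
#' @param alpha_mem weight of the running-integral term (default 1).
#' @param t_min smallest lag time included in the fit, in ps; default
#'   `res$dt` (skip the lag-0 point, where the one-sided derivative is
#'   least accurate).
#' @param bounds list with `gamma = c(lo, hi)` (u/ps) and
#'   `tau = c(lo, hi)` (ps) search ranges.
#' @param seed RNG seed; same inputs and seed give bitwise-identical
#'   parameters.
#' @param smooth_G use the alternation-free two-point average of G on the
#'   half-lag grid (default `TRUE`), see Details.
#' @param de_control list overriding the evolutionary-search settings
#'   `np` (population) and `maxiter` (generations).
#' @return a [memory_kernel()].  If two fitted memory times agree within
#'   1%, the components are merged with a warning.
#' @export
fit_multiexponential <- function(res, n_exp = 5L, alpha_mem = 1,
                                 t_min = NULL,
                                 bounds = list(gamma = c(1e-2, 1e7),
                                               tau = c(1e-3, 1e6)),
                                 seed = 1L, smooth_G = TRUE,
                                 de_control = list()) {
  stopifnot(inherits(res, "extraction_result"), n_exp >= 1L, n_exp <= 8L,
            alpha_mem >= 0)
  if (is.null(res$Gamma)) stop("Gamma not filled; run differentiate_G() first")
  if (is.null(t_min)) t_min <- res$dt
  tgrid <- (seq_along(res$G) - 1) * res$dt
  keep <- tgrid >= t_min
  if (sum(keep) < 2L * n_exp)
    stop("too few lags above t_min to constrain the fit")
  t_gam <- tgrid[keep]
  gam_d <- res$Gamma[keep]
  if (smooth_G) {
    nG <- length(res$G)
    t_G_all <- (seq_len(nG - 1L) - 0.5) * res$dt
    G_all <- (res$G[-1L] + res$G[-nG]) / 2
  } else {
    t_G_all <- tgrid
    G_all <- res$G
  }
  keepG <- t_G_all >= t_min
  t_G <- t_G_all[keepG]
  G_d <- G_all[keepG]
  w_gam <- max(abs(gam_d))^2
  w_G <- max(abs(G_d))^2
  n_exp <- as.integer(n_exp)

  model_loss <- function(p) {
    # p = (log10 gamma_1..n, log10 tau_1..n)
    gam <- 10^p[seq_len(n_exp)]
    tau <- 10^p[n_exp + seq_len(n_exp)]
    Km <- rep(0, length(t_gam)); Gm <- rep(0, length(t_G))
    for (i in seq_len(n_exp)) {
      Km <- Km + gam[i] / tau[i] * exp(-t_gam / tau[i])
      Gm <- Gm + gam[i] * (1 - exp(-t_G / tau[i]))
    }
    mean((Km - gam_d)^2) / w_gam + alpha_mem * mean((Gm - G_d)^2) / w_G
  }

  lower <- c(rep(log10(bounds$gamma[1L]), n_exp), rep(log10(bounds$tau[1L]), n_exp))
  upper <- c(rep(log10(bounds$gamma[2L]), n_exp), rep(log10(bounds$tau[2L]), n_exp))
  ctrl <- modifyList(list(np = max(10L * 2L * n_exp, 20L), maxiter = 250L),
                     de_control)
  set.seed(seed)
  de <- de_optimize(model_loss, lower, upper, np = ctrl$np,
                    maxiter = ctrl$maxiter)
  pol <- optim(de$par, model_loss, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 500L, factr = 1e4))
  p <- if (pol$value <= de$value) pol$par else de$par
  gam <- 10^p[seq_len(n_exp)]
  tau <- 10^p[n_exp + seq_len(n_exp)]
  ord <- order(tau)
  gam <- gam[ord]; tau <- tau[ord]
  # merge components whose memory times collapsed onto each other
  if (n_exp > 1L) {
    i <- 1L
    while (i < length(tau)) {
      if (tau[i + 1L] / tau[i] < 1.01) {
        warning(sprintf("components %d and %d collapsed (tau within 1%%); merged", i, i + 1L))
        tau[i] <- (gam[i] * tau[i] + gam[i + 1L] * tau[i + 1L]) / (gam[i] + gam[i + 1L])
        gam[i] <- gam[i] + gam[i + 1L]
        tau <- tau[-(i + 1L)]; gam <- gam[-(i + 1L)]
      } else i <- i + 1L
    }
  }
  memory_kernel(gam, tau)
}

#' Serialize a kernel as JSON
#' @param kernel a [memory_kernel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "memory_kernel"))
  jsonlite::write_json(list(gammas = kernel$gammas, taus = kernel$taus,
                            units = list(gamma = "u/ps", tau = "ps")),
                       path, digits = NA)
  invisible(path)
}

#' Read a kernel from JSON
#' @param path JSON written by [write_kernel()].
#' @return a [memory_kernel()].
#' @export
read_kernel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  memory_kernel(obj$gammas, obj$taus)
}
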