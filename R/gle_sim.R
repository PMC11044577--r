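#' Simulate the GLE via a Markovian embedding
#'
#' Integrates the generalized Langevin equation with a multiexponential
#' kernel by coupling the coordinate harmonically to one overdamped
#' auxiliary variable per exponential component:
#' \deqn{m\,dv = \big[-\nabla U(x) + \sum_i k_i (y_i - x)\big] dt, \quad
#'       \gamma_i\, dy_i = -k_i (y_i - x)\, dt + \sqrt{2 k_B T \gamma_i}\, dW_i,}
#' with \eqn{k_i = \gamma_i/\tau_i}.  Integrating out the \eqn{y_i} yields
#' exactly the kernel \eqn{\Gamma(t) = \sum_i (\gamma_i/\tau_i) e^{-t/\tau_i}}
#' with fluctuation-dissipation-consistent noise.  The integrator applies a
#' symmetric velocity-Verlet-type splitting to \eqn{(x, v)} and the exact
#' Ornstein-Uhlenbeck update to each auxiliary variable, which is
#' unconditionally stable in the \eqn{y_i} even for \eqn{\tau_i} close to
#' the integration step.
#'
#' Initialization draws \eqn{x_0} from the Boltzmann weight of the PMF,
#' \eqn{v_0} from Maxwell-Boltzmann, and each \eqn{y_i} from its
#' conditional equilibrium Gaussian (mean \eqn{x_0}, variance
#' \eqn{k_B T \tau_i/\gamma_i}), so equilibration transients are minimal;
#' `n_equil` steps are nevertheless discarded.
#'
#' @param kernel a [memory_kernel()].
#' @param pmf a `"pmf"` object (analytic polynomial or histogram-based).
#' @param mass effective mass in u.
#' @param kT thermal energy in kJ/mol (0 allowed: deterministic dynamics).
#' @param dt_sim integration step \eqn{\delta t} in ps (default 0.002, i.e.
#'   2 fs).  A warning (or error, see `stability`) is raised when it
#'   exceeds `min(tau)/10`.
#' @param n_steps number of production steps.
#' @param n_equil discarded equilibration steps (default 1e4).
#' @param seed integer seed; same seed gives a bitwise-identical
#'   trajectory.
#' @param x0,v0 optional explicit initial condition (nm, nm/ps); `NULL`
#'   samples from equilibrium as above.
#' @param out_stride record every `out_stride`-th step; the returned
#'   trajectory has time step `dt_sim * out_stride`.
#' @param store_velocities also record instantaneous velocities.
#' @param stability `"warn"` (default) or `"error"` for time-step checks.
#' @return a [trajectory()] with `meta` recording seed, `dt_sim`, stride
#'   and kernel parameters.
#' @export
simulate_gle <- function(kernel, pmf, mass, kT, dt_sim = 0.002,
                         n_steps, n_equil = 1e4, seed = 1L,
                         x0 = NULL, v0 = NULL, out_stride = 1L,
                         store_velocities = TRUE,
                         stability = c("warn", "error")) {
  stability <- match.arg(stability)
  stopifnot(inherits(kernel, "memory_kernel"), inherits(pmf, "pmf"),
            mass > 0, kT >= 0, dt_sim > 0, n_steps >= 1, out_stride >= 1)
  if (dt_sim > min(kernel$taus) / 10) {
    msg <- sprintf("dt_sim = %g ps exceeds min(tau)/10 = %g ps; kernel components may be under-resolved",
                   dt_sim, min(kernel$taus) / 10)
    if (stability == "error") stop(msg) else warning(msg)
  }
  set.seed(seed)
  if (is.null(x0))
    x0 <- if (kT > 0) sample_boltzmann(pmf, kT) else {
      xg <- seq(pmf$support[1L], pmf$support[2L], length.out = 4001L)
      xg[which.min(pmf_value(pmf, xg))]
    }
  if (is.null(v0)) v0 <- if (kT > 0) rnorm(1L, 0, sqrt(kT / mass)) else 0
  y0 <- x0 + if (kT > 0)
    rnorm(length(kernel$taus), 0, sqrt(kT * kernel$taus / kernel$gammas))
  else rep(0, length(kernel$taus))

  if (pmf$kind == "poly") {
    pot_type <- 0L
    grad_coefs <- pmf$grad_coefs
    gtab <- list(x0 = 0, dx = 1, g = c(0, 0))
  } else {
    pot_type <- 1L
    grad_coefs <- 0
    gtab <- pmf_gradient_table(pmf)
  }
  cpp_seed <- as.integer((seed * 2654435761) %% .Machine$integer.max)
  out <- gle_integrate_cpp(x0, v0, y0, mass, kT, dt_sim,
                           n_steps, as.integer(out_stride), n_equil,
                           kernel$gammas, kernel$taus,
                           pot_type, grad_coefs,
                           gtab$x0, gtab$dx, gtab$g,
                           cpp_seed, store_velocities)
  trajectory(out$x, dt = dt_sim * out_stride,
             velocities = if (store_velocities) out$v else NULL,
             meta = list(source = "gle_sim", seed = seed, dt_sim = dt_sim,
                         out_stride = out_stride,
                         kernel = list(gammas = kernel$gammas,
                                       taus = kernel$taus),
                         mass = mass, kT = kT,
                         velocity_scheme = if (store_velocities) "instantaneous" else NULL))
}

#' Fluctuation-dissipation check of the embedding's random force
#'
#' The random force of the embedded GLE is the force exerted by freely
#' relaxing auxiliary variables, i.e. the exact decomposition of
#' \eqn{\sum_i k_i (y_i - x)} with the feedback of the coordinate history
#' removed.  This routine runs a dedicated instrumented realization of
#' that decomposition (each auxiliary evolving as a stationary OU process
#' about a fixed coordinate), accumulates
#' \eqn{\langle F_R(0) F_R(n\,\delta t)\rangle}, and returns its ratio to
#' the fluctuation-dissipation prediction \eqn{k_B T\, \Gamma(n\,\delta t)}.
#' At equilibrium the ratio is 1 for all lags, within sampling error.
#'
#' @param kernel a [memory_kernel()].
#' @param kT thermal energy in kJ/mol (> 0).
#' @param dt_sim time step in ps.
#' @param n_steps number of recorded steps.
#' @param n_lags maximum lag index of the ratio.
#' @param seed RNG seed.
#' @return data.frame with columns `lag_ps`, `c_fr` (random-force
#'   autocorrelation), `kT_gamma` (prediction), `ratio`.
#' @export
check_fdt <- function(kernel, kT, dt_sim, n_steps, n_lags, seed = 1L) {
  stopifnot(inherits(kernel, "memory_kernel"), kT > 0)
  set.seed(seed)
  n_steps <- as.integer(n_steps)
  k <- kernel$gammas / kernel$taus
  FR <- rep(0, n_steps)
  for (i in seq_along(k)) {
    a <- exp(-dt_sim / kernel$taus[i])
    s <- sqrt(kT / k[i] * (1 - a^2))
    y0 <- rnorm(1L, 0, sqrt(kT / k[i]))
    innov <- rnorm(n_steps, 0, s)
    y <- as.numeric(filter(innov, a, method = "recursive", init = y0))
    FR <- FR + k[i] * y
  }
  c_fr <- crosscorr(FR, FR, dt_sim, n_lags)
  lag <- (0:n_lags) * dt_sim
  pred <- kT * kernel_gamma(kernel, lag)
  data.frame(lag_ps = lag, c_fr = c_fr, kT_gamma = pred,
             ratio = c_fr / pred)
}
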