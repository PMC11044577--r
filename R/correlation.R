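#' Stationary cross-correlation on the discrete lag grid
#'
#' Estimates \eqn{C[n] = \langle a_j b_{j+n} \rangle} for lags
#' \eqn{n = 0, \dots, n_{lags}} from a single pair of series (time average,
#' no ensemble averaging).  Computed via FFT with zero padding; identical to
#' the direct double loop to 1e-10 relative accuracy.
#'
#' The `"unbiased"` estimator divides lag n by (M - n), the `"biased"` one
#' by M.  Unbiased is the package default: only lags with M >> n are used
#' downstream, so the variance inflation is negligible, while the biased
#' estimator's systematic damping would distort the long-time tail entering
#' the Volterra inversion.
#'
#' @param a,b numeric series of equal length M.
#' @param dt time step in ps (recorded, not used in the estimate).
#' @param n_lags maximum lag index; must be < M.  The result has
#'   `n_lags + 1` entries for lags `0:n_lags`.
#' @param estimator `"unbiased"` or `"biased"`.
#' @return numeric vector of length `n_lags + 1`.
#' @export
crosscorr <- function(a, b, dt, n_lags, estimator = c("unbiased", "biased")) {
  estimator <- match.arg(estimator)
  a <- as.numeric(a); b <- as.numeric(b)
  M <- length(a)
  if (length(b) != M) stop("series must have equal length")
  if (n_lags >= M) stop("n_lags must be < series length")
  n <- nextn(M + n_lags + 1L, 2L)
  fa <- fft(c(a, rep(0, n - M)))
  fb <- fft(c(b, rep(0, n - M)))
  cc <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / n
  raw <- cc[seq_len(n_lags + 1L)]
  div <- if (estimator == "unbiased") M - 0:n_lags else rep(M, n_lags + 1L)
  raw / div
}

#' Correlation functions required by the extraction schemes
#'
#' Fills, on the common lag grid `0:n_lags * dt`:
#' \itemize{
#'   \item `cvv`: velocity autocorrelation \eqn{C^{vv}} in (nm/ps)^2,
#'   \item `cgradUv`: \eqn{\langle \nabla U(x(t)) v(0) \rangle},
#'   \item `cgradUx`: \eqn{\langle \nabla U(x(t)) x(0) \rangle},
#'   \item `cxx`: mean-removed position autocorrelation of
#'     \eqn{\bar x(t) = x(t) - \langle x \rangle} in nm^2, using the
#'     empirical mean of the supplied (possibly subsampled) series.
#' }
#' Velocities are not mean-subtracted by default (their equilibrium mean is
#' zero; set `demean_v = TRUE` to subtract the finite-sample mean).
#'
#' @param traj a [trajectory()] carrying velocities (see
#'   [estimate_velocities()]).
#' @param pmf a `"pmf"` object.
#' @param n_lags maximum lag index.
#' @param estimator passed to [crosscorr()].
#' @param demean_v subtract the empirical velocity mean first.
#' @return an object of class `"correlation_set"`.
#' @export
correlation_set <- function(traj, pmf, n_lags,
                            estimator = c("unbiased", "biased"),
                            demean_v = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$velocities))
    stop("trajectory has no velocities; run estimate_velocities() first")
  x <- traj$positions
  v <- traj$velocities
  if (demean_v) v <- v - mean(v)
  g <- grad_u_series(pmf, traj)
  xb <- x - mean(x)
  structure(list(
    dt = traj$dt, n_lags = as.integer(n_lags), estimator = estimator,
    cvv = crosscorr(v, v, traj$dt, n_lags, estimator),
    cgradUv = crosscorr(v, g, traj$dt, n_lags, estimator),
    cgradUx = crosscorr(x, g, traj$dt, n_lags, estimator),
    cxx = crosscorr(xb, xb, traj$dt, n_lags, estimator),
    demean_v = demean_v),
    class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf(paste0("correlation_set: lags 0..%d, dt = %g ps, %s estimator\n",
                     "  cvv[0] = %.5g (nm/ps)^2, cxx[0] = %.5g nm^2\n"),
              x$n_lags, x$dt, x$estimator, x$cvv[1L], x$cxx[1L]))
  invisible(x)
}

#' Serialize a correlation set as TSV
#'
#' Columns: `lag_ps, cvv, cgradUv, cgradUx, cxx`; header records estimator
#' and time step.
#'
#' @param corr a `"correlation_set"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_set <- function(corr, path) {
  stopifnot(inherits(corr, "correlation_set"))
  con <- file(path, "w")
  writeLines(sprintf("# memkernel correlation_set  dt_ps=%.10g  estimator=%s  demean_v=%s",
                     corr$dt, corr$estimator, corr$demean_v), con)
  writeLines("# lag_ps\tcvv\tcgradUv\tcgradUx\tcxx", con)
  tab <- data.frame(lag = (0:corr$n_lags) * corr$dt, cvv = corr$cvv,
                    cgUv = corr$cgradUv, cgUx = corr$cgradUx, cxx = corr$cxx)
  write.table(format(tab, digits = 10, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read back a serialized correlation set
#'
#' @param path TSV written by [write_correlation_set()].
#' @return a `"correlation_set"`.
#' @export
read_correlation_set <- function(path) {
  hdr <- readLines(path, n = 1L)
  dt <- as.numeric(sub(".*dt_ps=([0-9.eE+-]+).*", "\\1", hdr))
  est <- sub(".*estimator=([a-z]+).*", "\\1", hdr)
  tab <- read.table(path, comment.char = "#")
  structure(list(dt = dt, n_lags = nrow(tab) - 1L, estimator = est,
                 cvv = tab[[2L]], cgradUv = tab[[3L]], cgradUx = tab[[4L]],
                 cxx = tab[[5L]], demean_v = grepl("demean_v=TRUE", hdr)),
            class = "correlation_set")
}
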