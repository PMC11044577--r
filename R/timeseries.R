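#' Uniformly sampled scalar trajectory
#'
#' Container for a discretized one-dimensional reaction-coordinate time
#' series.  Positions are in nm, the time step `dt` in ps, optional
#' velocities in nm/ps.  All estimators in the package assume uniform
#' sampling.
#'
#' @param positions numeric vector of coordinate values in nm, length >= 2.
#' @param dt time step between consecutive samples in ps, > 0.
#' @param velocities optional numeric vector aligned with `positions`.
#' @param meta free-form provenance list (source, stride, seed, schemes).
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(positions, dt, velocities = NULL, meta = list()) {
  positions <- as.numeric(positions)
  if (length(positions) < 2L)
    stop("trajectory needs at least 2 positions")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (ps)")
  if (!is.null(velocities)) {
    velocities <- as.numeric(velocities)
    if (length(velocities) != length(positions))
      stop("velocities must align with positions (same length)")
  }
  structure(list(positions = positions, dt = as.numeric(dt),
                 velocities = velocities, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, dt = %g ps (%.4g ns total)%s\n",
              length(x$positions), x$dt,
              (length(x$positions) - 1) * x$dt / 1000,
              if (is.null(x$velocities)) "" else ", velocities stored"))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$positions)

#' Read a trajectory from delimited text
#'
#' One numeric column is read as positions (then `dt` must be given); two
#' columns are read as (time, position) and the time spacing, which must be
#' uniform to a relative tolerance of 1e-6, determines `dt` (overriding the
#' `dt` argument with a warning if they disagree).  Lines starting with `#`
#' are ignored.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` (whitespace) or `"csv"`.
#' @param dt time step in ps; required for one-column files.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "tsv", "csv"), dt = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("h5", "hdf5"))
      stop("HDF5 input is not supported by this build; ",
           "export the dataset to tsv/csv (columns: time, position)")
    format <- if (ext == "csv") "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else ""
  tab <- tryCatch(
    read.table(path, sep = sep, comment.char = "#",
               colClasses = "numeric", header = FALSE),
    error = function(e) stop("could not parse ", path, ": ", conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty trajectory file: ", path)
  if (ncol(tab) == 1L) {
    if (is.null(dt)) stop("one-column file requires an explicit dt")
    return(trajectory(tab[[1L]], dt = dt,
                      meta = list(source = path, format = format)))
  }
  tvec <- tab[[1L]]
  x <- tab[[2L]]
  dts <- diff(tvec)
  dt_file <- dts[1L]
  if (dt_file <= 0) stop("non-increasing time column")
  bad <- which(abs(dts - dt_file) > 1e-6 * abs(dt_file))
  if (length(bad) > 0L)
    stop(sprintf("non-uniform time at row %d", bad[1L] + 1L))
  if (!is.null(dt) && abs(dt - dt_file) > 1e-6 * dt_file)
    warning(sprintf("dt argument (%g) overridden by file time spacing (%g)",
                    dt, dt_file))
  trajectory(x, dt = dt_file, meta = list(source = path, format = format))
}

#' Write a trajectory as two-column TSV (time, position)
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# memkernel trajectory  dt_ps=%.10g  n=%d",
                     traj$dt, length(traj$positions)), con)
  t <- (seq_along(traj$positions) - 1) * traj$dt
  writeLines(sprintf("%.10g\t%.10g", t, traj$positions), con)
  invisible(path)
}

#' Subsample a trajectory with a fixed stride
#'
#' Keeps frames 0, stride, 2*stride, ... (frame 0 always retained, no random
#' phase) and multiplies `dt` by the stride.  Velocities are dropped: at the
#' coarser sampling interval they must be re-estimated with
#' [estimate_velocities()].
#'
#' @param traj a [trajectory()].
#' @param stride positive integer.
#' @return the subsampled [trajectory()].
#' @export
subsample <- function(traj, stride) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1 ||
      stride != round(stride))
    stop("stride must be a positive integer")
  stride <- as.integer(stride)
  idx <- seq.int(1L, length(traj$positions), by = stride)
  meta <- traj$meta
  meta$stride <- c(meta$stride, stride)
  trajectory(traj$positions[idx], dt = traj$dt * stride, meta = meta)
}

#' Estimate velocities by central differences
#'
#' Interior velocities are \eqn{v_n = (x_{n+1} - x_{n-1})/(2 \Delta t)}; the
#' two boundary samples are dropped from both positions and velocities so
#' that the pair stays aligned.  Central differences are used because they
#' are second-order and symmetric, preserving the time-reversal symmetry of
#' the velocity autocorrelation (one-sided differences bias C^vv(0)).
#'
#' @param traj a [trajectory()] with at least 3 frames.
#' @return a [trajectory()] of length `length(traj) - 2` with velocities.
#' @export
estimate_velocities <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  x <- traj$positions
  M <- length(x)
  if (M < 3L) stop("need at least 3 positions for central differences")
  v <- (x[3:M] - x[1:(M - 2L)]) / (2 * traj$dt)
  meta <- traj$meta
  meta$velocity_scheme <- "central-difference"
  trajectory(x[2:(M - 1L)], dt = traj$dt, velocities = v, meta = meta)
}
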