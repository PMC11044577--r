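#' Validate a pipeline run configuration
#'
#' Checks the configuration list (or YAML file) driving
#' [run_volterra_pipeline()] / [run_gpo_pipeline()].  Violations raise a
#' condition of class `"memkernel_config_error"` whose message names the
#' offending key; the command-line wrapper maps these to exit status 2.
#'
#' @param config list or path to a YAML file.
#' @return the validated configuration list, invisibly.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  fail <- function(key, why)
    stop(structure(class = c("memkernel_config_error", "error", "condition"),
                   list(message = sprintf("config key '%s': %s", key, why),
                        call = NULL)))
  if (!is.list(config)) fail("(root)", "must be a mapping")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    fail("seed", "must be an integer")
  if (is.null(config$out_dir)) fail("out_dir", "is required")
  num_pos <- function(key, val) {
    if (!is.null(val) && (!is.numeric(val) || val <= 0))
      fail(key, "must be a positive number")
  }
  num_pos("correlate.dt", config$correlate$dt)
  num_pos("correlate.stride", config$correlate$stride)
  num_pos("volterra.mass", config$volterra$mass)
  num_pos("pmf.kT", config$pmf$kT)
  num_pos("pmf.n_bins", config$pmf$n_bins)
  num_pos("gpo.dt", config$gpo$dt)
  num_pos("gpo.budget", config$gpo$budget)
  if (is.null(config$trajectory$path) && is.null(config$synth))
    fail("trajectory.path", "either a trajectory file or a synth block is required")
  invisible(config)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "memkernel_config_error")) stop(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

pipeline_inputs <- function(config) {
  # trajectory + pmf from either a file or the synthetic generator; the PMF
  # is always taken from the full-resolution data (or analytically for
  # synthetic systems), even when correlations use subsampled data.
  if (!is.null(config$trajectory$path)) {
    traj <- read_trajectory(config$trajectory$path,
                            format = if (is.null(config$trajectory$format))
                              "auto" else config$trajectory$format,
                            dt = config$trajectory$dt)
    kT <- if (is.null(config$pmf$kT)) 2.494 else config$pmf$kT
    pmf <- estimate_pmf(traj, kT = kT,
                        n_bins = if (is.null(config$pmf$n_bins)) 100
                        else config$pmf$n_bins,
                        spar = config$pmf$spar)
    list(traj = traj, pmf = pmf, kT = kT)
  } else {
    sp <- config$synth
    spec <- if (!is.null(sp$spec_path)) read_synthetic_spec(sp$spec_path)
    else default_ala9_like(n_steps = if (is.null(sp$n_steps)) 5e6
                           else sp$n_steps,
                           seed = config$seed)
    ref <- make_reference(spec)
    list(traj = ref$trajectory, pmf = ref$pmf, kT = spec$kT, spec = spec)
  }
}

write_manifest <- function(config, outputs, dir) {
  manifest <- list(
    package = "memkernel",
    version = as.character(utils::packageVersion("memkernel")),
    seed = config$seed,
    parameters = config,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.path(dir, "manifest.json")
}

#' Run the Volterra extraction pipeline
#'
#' Stages: load (or synthesize) the trajectory, estimate the PMF from the
#' full-resolution data, subsample to the analysis discretization,
#' estimate velocities, compute correlation functions, invert the Volterra
#' equation, differentiate, fit a multiexponential kernel and report time
#' scales.  Writes `correlations.tsv`, `extraction.tsv`, `kernel.json`,
#' `timescales.json` and a `manifest.json` with md5 checksums, parameters
#' and seeds sufficient to reproduce the run exactly.
#'
#' @param config list or YAML path; see [validate_run_config()].  Keys:
#'   `trajectory` (path/format/dt) or `synth`, `pmf` (kT/n_bins/spar),
#'   `correlate` (stride, n_lags), `volterra` (mass, identity handling),
#'   `fit` (n_exp, alpha_mem, t_min), `timescales` (L), `seed`, `out_dir`.
#' @return list with `kernel`, `timescales`, `extraction`, `manifest`
#'   (invisibly).
#' @export
run_volterra_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- run_stage("input", pipeline_inputs(config))
  stride <- if (is.null(config$correlate$stride)) 1L else config$correlate$stride
  tr <- if (stride > 1L) subsample(inp$traj, stride) else inp$traj
  tr <- run_stage("velocities", estimate_velocities(tr))
  n_lags <- if (is.null(config$correlate$n_lags))
    min(500L, length(tr) %/% 10L) else config$correlate$n_lags
  corr <- run_stage("correlate",
                    correlation_set(tr, inp$pmf, n_lags = n_lags))
  mass <- if (is.null(config$volterra$mass)) 31.4 else config$volterra$mass
  res <- run_stage("volterra", {
    r <- solve_G(corr, mass = mass)
    differentiate_G(r)
  })
  n_exp <- if (is.null(config$fit$n_exp)) 5L else config$fit$n_exp
  kern <- run_stage("fit",
    fit_multiexponential(res, n_exp = n_exp,
                         alpha_mem = if (is.null(config$fit$alpha_mem)) 1
                         else config$fit$alpha_mem,
                         t_min = config$fit$t_min,
                         seed = config$seed))
  L <- if (is.null(config$timescales$L)) 0.22 else config$timescales$L
  ts <- timescales(kern, mass = mass, kT = inp$kT, L = L)
  outs <- c(
    run_stage("write", write_correlation_set(corr, file.path(config$out_dir, "correlations.tsv"))),
    write_extraction(res, file.path(config$out_dir, "extraction.tsv")),
    write_kernel(kern, file.path(config$out_dir, "kernel.json")),
    {
      jsonlite::write_json(unclass(ts), file.path(config$out_dir, "timescales.json"),
                           auto_unbox = TRUE, digits = NA)
      file.path(config$out_dir, "timescales.json")
    })
  manifest <- write_manifest(config, as.list(outs), config$out_dir)
  invisible(list(kernel = kern, timescales = ts, extraction = res,
                 correlations = corr, manifest = manifest))
}

#' Run the GPO extraction pipeline
#'
#' Computes reference correlation functions at the requested
#' discretization and optimizes GLE parameters to match them (see
#' [gpo_extract_kernel()]).  Writes `ref_correlations.tsv`, the run ledger
#' (`samples.jsonl`, `summary.json`), `kernel.json` and `manifest.json`.
#'
#' @param config list or YAML path; keys as in [run_volterra_pipeline()]
#'   plus a `gpo` block (`dt`, `kind`, `alpha`, `n_vv`, `n_xx`, `n_exp`,
#'   `budget`, `n_init`, `best_k`, `dt_sim`, `sim_time`, `bounds`).
#' @return list with `kernel`, `run`, `manifest` (invisibly).
#' @export
run_gpo_pipeline <- function(config) {
  config <- validate_run_config(config)
  if (is.null(config$gpo$dt))
    stop(structure(class = c("memkernel_config_error", "error", "condition"),
                   list(message = "config key 'gpo.dt': is required", call = NULL)))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- run_stage("input", pipeline_inputs(config))
  g <- config$gpo
  stride <- max(1L, round(g$dt / inp$traj$dt))
  tr <- estimate_velocities(subsample(inp$traj, stride))
  n_lags <- min(length(tr) %/% 4L,
                if (is.null(g$n_lags)) 200L else g$n_lags)
  ref_corr <- run_stage("correlate",
                        correlation_set(tr, inp$pmf, n_lags = n_lags))
  n_vv <- if (is.null(g$n_vv)) default_n_samples(ref_corr$cvv) else g$n_vv
  n_xx <- if (is.null(g$n_xx)) default_n_samples(ref_corr$cxx) else g$n_xx
  spec <- loss_spec(kind = if (is.null(g$kind)) "combined" else g$kind,
                    alpha = if (is.null(g$alpha)) 1 else g$alpha,
                    n_vv = n_vv, n_xx = n_xx, dt = tr$dt)
  sim_template <- list(pmf = inp$pmf,
                       mass = if (is.null(config$volterra$mass)) 31.4
                       else config$volterra$mass,
                       kT = inp$kT,
                       dt_sim = if (is.null(g$dt_sim)) tr$dt / 500 else g$dt_sim,
                       sim_time = if (is.null(g$sim_time))
                         2000 * n_xx * tr$dt else g$sim_time)
  res <- run_stage("gpo",
    gpo_extract_kernel(ref_corr, spec, sim_template,
                       n_exp = if (is.null(g$n_exp)) 2L else g$n_exp,
                       bounds = if (is.null(g$bounds))
                         list(gamma = c(1e2, 1e6), tau = c(1, 1e4))
                       else g$bounds,
                       budget = if (is.null(g$budget)) 60L else g$budget,
                       n_init = if (is.null(g$n_init)) 30L else g$n_init,
                       best_k = if (is.null(g$best_k)) 10L else g$best_k,
                       seed = config$seed))
  outs <- c(
    write_correlation_set(ref_corr, file.path(config$out_dir, "ref_correlations.tsv")),
    write_kernel(res$kernel, file.path(config$out_dir, "kernel.json")))
  write_gpo_run(res$run, config$out_dir)
  outs <- c(outs, file.path(config$out_dir, c("samples.jsonl", "summary.json")))
  manifest <- write_manifest(config, as.list(outs), config$out_dir)
  invisible(list(kernel = res$kernel, run = res$run, manifest = manifest))
}
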