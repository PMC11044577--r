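kT <- 2.494

test_that("correlation_loss is the normalized mean-squared deviation", {
  expect_equal(correlation_loss(c(1, 0.5), c(1, 0.5), 2), 0)
  expect_equal(correlation_loss(c(1, 0.5), c(1, 0.3), 2), 0.02)
  # scale invariance: doubling both series leaves the loss unchanged
  expect_equal(correlation_loss(2 * c(1, 0.5), 2 * c(1, 0.3), 2), 0.02)
  expect_error(correlation_loss(c(0, 1), c(1, 1), 2), "zero t = 0")
  expect_error(correlation_loss(c(1, 1), c(1, 1), 5), "shorter")
  expect_error(correlation_loss(c(1, 1), c(1, 1), 0), "n_samples")
})

test_that("theta vectors map to kernels and back", {
  k <- kernel_from_theta(c(10, 0.5, 30, 8))
  expect_equal(k$gammas, c(10, 30))
  expect_equal(k$taus, c(0.5, 8))
  expect_error(kernel_from_theta(c(1, 2, 3)), "even length")
})

test_that("a noiseless quadratic objective is minimized to within 1%", {
  # test hook bypassing simulation: smooth deterministic loss in theta
  theta_star <- 3
  objective <- function(theta, seed) (log10(theta) - log10(theta_star))^2 + 1e-12
  run <- gpo_optimize(objective, lower = 0.05, upper = 500, budget = 30,
                      n_init = 10, best_k = 3, seed = 44, revalidate = FALSE)
  best <- run$samples$theta1[which.min(run$samples$loss)]
  expect_lt(abs(best - theta_star) / theta_star, 0.01)
})

test_that("a degenerate budget returns exactly the initial uniform samples", {
  objective <- function(theta, seed) sum(theta)
  run <- gpo_optimize(objective, lower = c(1, 1), upper = c(10, 10),
                      budget = 5, n_init = 5, best_k = 2, seed = 45,
                      revalidate = FALSE)
  expect_equal(nrow(run$samples), 5)
  expect_true(all(run$samples$phase == "init"))
})

test_that("runs are reproducible: same seeds give identical ledgers", {
  objective <- function(theta, seed) (log10(theta[1]) - 1)^2 + (log10(theta[2]) + 1)^2
  a <- gpo_optimize(objective, c(0.01, 0.01), c(100, 100), budget = 16,
                    n_init = 8, best_k = 3, seed = 46)
  b <- gpo_optimize(objective, c(0.01, 0.01), c(100, 100), budget = 16,
                    n_init = 8, best_k = 3, seed = 46)
  expect_identical(a$samples, b$samples)
  expect_identical(a$validation, b$validation)
})

# shared small reference for the simulation-backed tests: harmonic well,
# single-exponential ground truth, coarse discretization dt = 5 tau
gpo_harmonic_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    kern <- memory_kernel(1e4, 100)
    pmf <- pmf_polynomial(c(0, 0, 2), kT = kT, support = c(-6, 6))  # k = 4
    mass <- 2000
    ref <- simulate_gle(kern, pmf, mass, kT, dt_sim = 2.5, n_steps = 4e6,
                        out_stride = 200, seed = 47)   # dt = 500 ps, 10 us
    refv <- estimate_velocities(ref)
    ref_corr <- correlation_set(refv, pmf, n_lags = 40)
    cache <<- list(kern = kern, pmf = pmf, mass = mass, ref = ref,
                   ref_corr = ref_corr,
                   simt = list(pmf = pmf, mass = mass, kT = kT, dt_sim = 2.5,
                               sim_time = 2.5e6, n_equil = 2e4))
    cache
  }
})

test_that("evaluate_theta orders matched above badly mismatched parameters", {
  fx <- gpo_harmonic_fixture()
  spec <- loss_spec("combined", alpha = 1, n_vv = 5,
                    n_xx = default_n_samples(fx$ref_corr$cxx), dt = 500)
  l_true <- evaluate_theta(c(1e4, 100), fx$ref_corr, spec, fx$simt, seed = 48)
  l_small <- evaluate_theta(c(100, 100), fx$ref_corr, spec, fx$simt, seed = 48)
  expect_lt(l_true, l_small)
  # self-consistency floor: truth scores close to the split-half noise level
  half <- length(fx$ref$positions) %/% 2
  h1 <- trajectory(fx$ref$positions[1:half], dt = 500)
  h2 <- trajectory(fx$ref$positions[(half + 1):(2 * half)], dt = 500)
  cxx1 <- {xb <- h1$positions - mean(h1$positions); crosscorr(xb, xb, 500, spec$n_xx - 1)}
  cxx2 <- {xb <- h2$positions - mean(h2$positions); crosscorr(xb, xb, 500, spec$n_xx - 1)}
  floor_xx <- correlation_loss(cxx1, cxx2, spec$n_xx)
  expect_lt(l_true, 5 * (floor_xx + 1e-4))
})

test_that("evaluate_theta validates its inputs", {
  fx <- gpo_harmonic_fixture()
  expect_error(loss_spec("xx", n_xx = 0, dt = 500), "n_xx")
  bad_spec <- loss_spec("xx", n_xx = 5, dt = 123)
  expect_error(evaluate_theta(c(1e4, 100), fx$ref_corr, bad_spec, fx$simt),
               "does not match")
})

test_that("GPO recovers the total friction of a single-exponential reference", {
  fx <- gpo_harmonic_fixture()
  spec <- loss_spec("combined", alpha = 1, n_vv = 5,
                    n_xx = default_n_samples(fx$ref_corr$cxx), dt = 500)
  res <- gpo_extract_kernel(fx$ref_corr, spec, fx$simt, n_exp = 2,
                            budget = 60, n_init = 30, best_k = 10, seed = 49)
  expect_equal(gamma_tot(res$kernel), 1e4, tolerance = 0.25)
  expect_lte(nrow(res$run$samples), 60)
  expect_equal(sort(res$run$validation$idx), sort(res$run$best_idx))
})

test_that("the GPO run ledger serializes", {
  objective <- function(theta, seed) (log10(theta) - 1)^2
  run <- gpo_optimize(objective, 0.1, 100, budget = 8, n_init = 5,
                      best_k = 2, seed = 50)
  d <- tempfile()
  write_gpo_run(run, d)
  expect_true(file.exists(file.path(d, "samples.jsonl")))
  expect_equal(length(readLines(file.path(d, "samples.jsonl"))), 8)
  s <- jsonlite::read_json(file.path(d, "summary.json"), simplifyVector = TRUE)
  expect_equal(s$budget, 8)
})
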