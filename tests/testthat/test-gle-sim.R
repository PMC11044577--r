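kT <- 2.494

test_that("zero temperature at a minimum leaves the system at rest", {
  kern <- memory_kernel(c(10, 20), c(1, 5))
  pmf <- pmf_polynomial(c(0, 0, 50), kT = kT, support = c(-1, 1))
  tr <- simulate_gle(kern, pmf, mass = 31.4, kT = 0, dt_sim = 0.01,
                     n_steps = 1e4, n_equil = 0, seed = 1, x0 = 0, v0 = 0)
  expect_equal(max(abs(tr$positions)), 0)
  expect_equal(max(abs(tr$velocities)), 0)
})

test_that("equipartition holds in a harmonic well within 3 standard errors", {
  k <- 100
  kern <- memory_kernel(c(100, 400), c(1, 10))
  pmf <- pmf_polynomial(c(0, 0, k / 2), kT = kT, support = c(-1, 1))
  tr <- simulate_gle(kern, pmf, mass = 31.4, kT = kT, dt_sim = 0.01,
                     n_steps = 4e6, out_stride = 2, seed = 2)
  blocks <- function(v) {
    m <- matrix(v[seq_len(20 * (length(v) %/% 20))], ncol = 20)
    bm <- colMeans(m)
    c(mean(bm), sd(bm) / sqrt(20))
  }
  bx <- blocks(tr$positions^2)
  expect_lt(abs(bx[1] - kT / k), 3 * bx[2])
  bv <- blocks(tr$velocities^2)
  expect_lt(abs(bv[1] - kT / 31.4), 3 * bv[2] + 0.01 * kT / 31.4)
})

test_that("trajectories are bitwise reproducible under the seed", {
  sys <- benchmark_system()
  a <- simulate_gle(sys$kernel, sys$pmf, sys$mass, sys$kT, dt_sim = 0.2,
                    n_steps = 1e4, seed = 9)
  b <- simulate_gle(sys$kernel, sys$pmf, sys$mass, sys$kT, dt_sim = 0.2,
                    n_steps = 1e4, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  c3 <- simulate_gle(sys$kernel, sys$pmf, sys$mass, sys$kT, dt_sim = 0.2,
                     n_steps = 1e4, seed = 10)
  expect_false(identical(a$positions, c3$positions))
})

test_that("the stationary histogram matches the Boltzmann weight in a double well", {
  sys <- benchmark_system()
  tr <- simulate_gle(sys$kernel, sys$pmf, sys$mass, sys$kT,
                     dt_sim = sys$dt_sim, n_steps = 3e6, out_stride = 20,
                     seed = 3)
  edges <- seq(0.2, 1.15, length.out = 26)
  counts <- tabulate(findInterval(tr$positions, edges), nbins = 26)[1:25]
  centers <- (edges[-1] + edges[-26]) / 2
  w <- exp(-pmf_value(sys$pmf, centers) / sys$kT)
  expected <- sum(counts) * w / sum(w)
  # block-wise effective sample size: positions decorrelate over ~ the
  # barrier-crossing time; chi-square on the thinned series
  thin <- tr$positions[seq(1, length(tr$positions), by = 200)]
  counts_t <- tabulate(findInterval(thin, edges), nbins = 26)[1:25]
  expected_t <- sum(counts_t) * w / sum(w)
  keep <- expected_t >= 5
  chi2 <- sum((counts_t[keep] - expected_t[keep])^2 / expected_t[keep])
  p <- pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("harmonic-well velocity autocorrelation matches the linear-embedding oracle", {
  K <- 100; gam <- 20; tau <- 5; mass <- 31.4
  kern <- memory_kernel(gam, tau)
  pmf <- pmf_polynomial(c(0, 0, K / 2), kT = kT, support = c(-1.5, 1.5))
  tr <- simulate_gle(kern, pmf, mass, kT, dt_sim = 0.01, n_steps = 6e6,
                     out_stride = 10, seed = 14)
  cvv <- crosscorr(tr$velocities, tr$velocities, 0.1, 150)
  oracle <- embedding_corr(K, gam, tau, mass, kT)
  lag <- (0:150) * 0.1
  expect_equal(cvv / cvv[1], oracle(lag) / oracle(0), tolerance = 0.03)
  # the amplitude converges on the slow energy-exchange time scale of the
  # weakly damped oscillator, so it carries a larger sampling error
  expect_equal(cvv[1], kT / mass, tolerance = 0.10)
})

test_that("the generated random force obeys the fluctuation-dissipation theorem", {
  kern <- memory_kernel(c(100, 400), c(1, 10))
  f <- check_fdt(kern, kT = kT, dt_sim = 0.05, n_steps = 4e6, n_lags = 200,
                 seed = 5)
  sel <- f$lag_ps <= 30
  expect_lt(abs(mean(f$ratio[sel]) - 1), 0.05)
  expect_lt(max(abs(f$ratio[sel] - 1)), 0.15)
  # t = 0 value: <F_R^2> = kT * sum(gamma_i / tau_i)
  expect_equal(f$c_fr[1] / kT, 100 / 1 + 400 / 10, tolerance = 0.02)
})

test_that("the random-force variance vanishes with temperature", {
  kern <- memory_kernel(50, 2)
  f_hot <- check_fdt(kern, kT = kT, dt_sim = 0.05, n_steps = 1e5,
                     n_lags = 10, seed = 6)
  f_cold <- check_fdt(kern, kT = kT * 1e-6, dt_sim = 0.05, n_steps = 1e5,
                      n_lags = 10, seed = 6)
  expect_lt(f_cold$c_fr[1], 2e-6 * f_hot$c_fr[1])
})

test_that("unstable configurations are reported, not silently produced", {
  kern <- memory_kernel(10, 100)
  pmf <- pmf_polynomial(c(0, 0, 5e5), kT = kT, support = c(-1, 1))  # stiff
  expect_error(
    suppressWarnings(simulate_gle(kern, pmf, mass = 1, kT = kT,
                                  dt_sim = 0.5, n_steps = 1e5, seed = 1,
                                  x0 = 0.5, v0 = 0)),
    "diverged")
  soft <- pmf_polynomial(c(0, 0, 5), kT = kT, support = c(-1, 1))
  expect_warning(simulate_gle(kern, soft, mass = 5000, kT = kT,
                              dt_sim = 20, n_steps = 100, seed = 1),
                 "min\\(tau\\)/10")
  expect_error(simulate_gle(kern, soft, mass = 5000, kT = kT, dt_sim = 20,
                            n_steps = 100, seed = 1, stability = "error"),
               "min\\(tau\\)/10")
})
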