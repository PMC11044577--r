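# The memory-function parameters printed for the fine-resolution helix
# coordinate benchmark; used as arithmetic inputs throughout.
bench_gammas <- c(2.2e3, 4.4e4, 2.4e5, 6.0e4, 4.6e3)
bench_taus <- c(0.007, 18, 370, 4100, 5700)

test_that("gamma_tot and tau_mem evaluate the analytic moments", {
  k <- memory_kernel(bench_gammas, bench_taus)
  expect_equal(gamma_tot(k), sum(bench_gammas))
  expect_equal(signif(gamma_tot(k), 2), 3.5e5)
  expect_equal(tau_mem(k), sum(bench_gammas * bench_taus) / sum(bench_gammas))
  expect_equal(gamma_tot(memory_kernel(7, 2)), 7)
  expect_equal(gamma_tot(memory_kernel(c(0, 0), c(1, 2))), 0)
  expect_equal(tau_mem(memory_kernel(5, 3.3)), 3.3)
  expect_error(tau_mem(memory_kernel(0, 1)), "zero")
})

test_that("components are stored sorted by ascending memory time", {
  k <- memory_kernel(c(5, 1), c(10, 0.1))
  expect_equal(k$taus, c(0.1, 10))
  expect_equal(k$gammas, c(1, 5))
  expect_error(memory_kernel(1, -1), "positive")
  expect_error(memory_kernel(c(1, 2), 1), "equal length")
})

test_that("analytic kernel functions agree with numerical quadrature of the defining integrals", {
  k <- memory_kernel(c(10, 40), c(0.5, 6))
  tg <- seq(0, 100 * max(k$taus), length.out = 1e5)
  gam <- kernel_gamma(k, tg)
  expect_equal(pracma::trapz(tg, gam), gamma_tot(k), tolerance = 1e-3)
  expect_equal(pracma::trapz(tg, tg * gam) / pracma::trapz(tg, gam),
               tau_mem(k), tolerance = 1e-3)
  # G(t) equals the running trapezoid of Gamma
  G_num <- pracma::cumtrapz(tg, gam)[, 1]
  i <- c(5000, 20000, 99999)
  expect_equal(kernel_G(k, tg[i]), G_num[i], tolerance = 1e-3)
})

test_that("time scales and kinetic regime follow the heuristic boundaries", {
  k <- memory_kernel(bench_gammas, bench_taus)
  ts <- timescales(k, mass = 31.4, kT = 2.494, L = 0.22)
  expect_equal(signif(ts$tau_mem, 1), 1000)       # prints as 1 ns
  expect_equal(round(ts$tau_D / 1000, 1), 6.8)    # ns
  expect_equal(round(ts$tau_m * 1000, 2), 0.09)   # fs
  expect_equal(ts$regime, "speedup")

  expect_equal(timescales(memory_kernel(100, 1), 31.4, 2.494, L = 0)$regime,
               "slowdown")
  markov <- timescales(memory_kernel(100, 0.001), 31.4, 2.494, L = 1)
  expect_equal(markov$regime, "markovian")
  expect_error(timescales(memory_kernel(0, 1), 1, 1, 1), "zero")
})

test_that("fitting recovers a single-exponential kernel from its own curves", {
  k <- memory_kernel(100, 10)
  dt <- 0.5; nl <- 200
  tg <- (0:nl) * dt
  res <- structure(list(dt = dt, G = kernel_G(k, tg),
                        Gamma = kernel_gamma(k, tg), mass = 31.4,
                        mass_used = 31.4, scheme = list(), n_lags = nl),
                   class = "extraction_result")
  fit <- fit_multiexponential(res, n_exp = 1, seed = 2)
  expect_equal(fit$gammas, 100, tolerance = 0.01)
  expect_equal(fit$taus, 10, tolerance = 0.01)
  # seed determinism is bitwise
  fit2 <- fit_multiexponential(res, n_exp = 1, seed = 2)
  expect_identical(fit$gammas, fit2$gammas)
  expect_identical(fit$taus, fit2$taus)
})

test_that("well-separated double-exponential kernels are recovered accurately", {
  k <- memory_kernel(c(50, 200), c(1, 100))
  dt <- 0.25; nl <- 2000
  tg <- (0:nl) * dt
  res <- structure(list(dt = dt, G = kernel_G(k, tg),
                        Gamma = kernel_gamma(k, tg), mass = 31.4,
                        mass_used = 31.4, scheme = list(), n_lags = nl),
                   class = "extraction_result")
  fit <- fit_multiexponential(res, n_exp = 2, seed = 5)
  expect_equal(gamma_tot(fit), 250, tolerance = 0.02)
  expect_equal(tau_mem(fit), tau_mem(k), tolerance = 0.05)
})

test_that("constant-Gamma data drives a 1-exponential fit to the long-tau limit", {
  dt <- 0.5; nl <- 100
  tg <- (0:nl) * dt
  res <- structure(list(dt = dt, G = 4 * tg, Gamma = rep(4, nl + 1),
                        mass = 1, mass_used = 1, scheme = list(), n_lags = nl),
                   class = "extraction_result")
  fit <- fit_multiexponential(res, n_exp = 1, seed = 3,
                              bounds = list(gamma = c(1e-2, 1e9),
                                            tau = c(1e-3, 1e6)))
  expect_gt(fit$taus, 1e3)    # far beyond the data window
  expect_equal(kernel_gamma(fit, tg[tg >= dt]), rep(4, sum(tg >= dt)),
               tolerance = 0.05)
})

test_that("collapsed components are merged with a warning", {
  k <- memory_kernel(80, 5)
  dt <- 0.5; nl <- 100
  tg <- (0:nl) * dt
  res <- structure(list(dt = dt, G = kernel_G(k, tg),
                        Gamma = kernel_gamma(k, tg), mass = 1,
                        mass_used = 1, scheme = list(), n_lags = nl),
                   class = "extraction_result")
  expect_warning(
    fit <- fit_multiexponential(res, n_exp = 2, seed = 7,
                                bounds = list(gamma = c(1, 1e3),
                                              tau = c(4.9, 5.1))),
    "merged")
  expect_length(fit$taus, 1)
  expect_equal(gamma_tot(fit), 80, tolerance = 0.02)
})

test_that("kernel JSON serialization round-trips", {
  k <- memory_kernel(c(3, 9), c(0.4, 8))
  p <- tempfile(fileext = ".json")
  write_kernel(k, p)
  back <- read_kernel(p)
  expect_equal(back$gammas, k$gammas)
  expect_equal(back$taus, k$taus)
})
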