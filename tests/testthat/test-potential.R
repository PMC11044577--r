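kT <- 2.494

test_that("flat sampling gives a flat potential with vanishing gradient", {
  set.seed(1)
  tr <- trajectory(runif(2e5), dt = 1)
  pmf <- estimate_pmf(tr, kT = kT, n_bins = 20)
  xg <- seq(0.1, 0.9, length.out = 50)
  expect_lt(diff(range(pmf_value(pmf, xg))), 0.15 * kT)
  expect_lt(max(abs(pmf_gradient(pmf, xg))), 2.5)  # kJ/mol/nm, noise scale
})

test_that("Boltzmann inversion of Gaussian samples recovers the harmonic curvature", {
  set.seed(2)
  sigma <- 0.1
  tr <- trajectory(rnorm(1e6, 0, sigma), dt = 1)
  pmf <- estimate_pmf(tr, kT = kT, n_bins = 60)
  # curvature near the minimum from a quadratic fit of U(x) within +-1 sigma
  xg <- seq(-sigma, sigma, length.out = 81)
  fit <- lm(pmf_value(pmf, xg) ~ poly(xg, 2, raw = TRUE))
  curv <- 2 * coef(fit)[[3]]
  expect_equal(curv, kT / sigma^2, tolerance = 0.05)
})

test_that("histogram log-ratios between bins equal free-energy differences", {
  # five bins with known occupation counts; U differences are -kT log ratios
  counts <- c(200, round(200 * exp(1)), 300, 250, 220)
  centers <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  x <- rep(centers, counts)
  pmf <- estimate_pmf(trajectory(x, dt = 1), kT = kT, n_bins = 5)
  expect_equal(pmf$u_values[1] - pmf$u_values[2],
               kT * log(counts[2] / counts[1]), tolerance = 1e-6)
  expect_equal(pmf$u_values[3] - pmf$u_values[4],
               -kT * log(counts[3] / counts[4]), tolerance = 1e-6)
})

test_that("interior empty bins are refused with advice to lower n_bins", {
  x <- c(runif(500, 0, 0.3), runif(500, 0.7, 1))
  expect_error(estimate_pmf(trajectory(x, dt = 1), kT = kT, n_bins = 20),
               "lower n_bins")
})

test_that("polynomial potentials evaluate exactly", {
  k <- 100
  pmf <- pmf_polynomial(c(0, 0, k / 2), kT = kT, support = c(-1, 1))
  expect_equal(pmf_gradient(pmf, c(-1, 0, 1)), c(-k, 0, k))
  expect_equal(pmf_value(pmf, 0.5), k / 8)
  flat <- pmf_polynomial(c(0, 0, 1e-12), kT = kT, support = c(-1, 1))
  expect_equal(grad_u_series(flat, trajectory(c(0.1, -0.4, 0.2), dt = 1)),
               c(0.1, -0.4, 0.2) * 2e-12, tolerance = 1e-20)
  expect_error(pmf_polynomial(c(0, 1), kT = kT), "confining")
  expect_error(pmf_polynomial(c(0, 0, -1), kT = kT), "confining")
})

test_that("spline gradient matches finite differences of the fitted profile", {
  set.seed(3)
  tr <- trajectory(rnorm(2e5, 0.5, 0.12), dt = 1)
  pmf <- estimate_pmf(tr, kT = kT, n_bins = 40)
  xg <- seq(pmf$support[1] + 0.02, pmf$support[2] - 0.02, length.out = 60)
  h <- 1e-5
  fd <- (pmf_value(pmf, xg + h) - pmf_value(pmf, xg - h)) / (2 * h)
  expect_equal(pmf_gradient(pmf, xg), fd, tolerance = 1e-4)
})

test_that("harmonic walls extend the profile continuously and confiningly", {
  set.seed(5)
  tr <- trajectory(rnorm(5e4, 0, 0.1), dt = 1)
  pmf <- estimate_pmf(tr, kT = kT, n_bins = 30)
  lo <- pmf$support[1]
  g_in <- pmf_gradient(pmf, lo + 1e-9)
  g_out <- pmf_gradient(pmf, lo - 1e-9)
  expect_equal(g_in, g_out, tolerance = 1e-3)
  # beyond the wall the potential keeps rising
  expect_gt(pmf_value(pmf, lo - 0.2), pmf_value(pmf, lo - 0.1))
  expect_gt(pmf_value(pmf, lo - 0.1), pmf_value(pmf, lo))
})

test_that("grad_u_series covers out-of-histogram excursions", {
  set.seed(6)
  tr <- trajectory(rnorm(5e4, 0, 0.1), dt = 1)
  pmf <- estimate_pmf(tr, kT = kT, n_bins = 30)
  probe <- trajectory(c(-5, 0, 5), dt = 1)
  g <- grad_u_series(pmf, probe)
  expect_length(g, 3)
  expect_true(all(is.finite(g)))
  expect_lt(g[1], 0)
  expect_gt(g[3], 0)
})

test_that("equilibrium gradient averages to zero over a well-sampled trajectory", {
  sys <- benchmark_system()
  tr <- simulate_gle(sys$kernel, sys$pmf, sys$mass, sys$kT,
                     dt_sim = sys$dt_sim, n_steps = 4e5, out_stride = 10,
                     seed = 8)
  g <- grad_u_series(sys$pmf, tr)
  expect_lt(abs(mean(g)), 3 * sd(g) / sqrt(sum(abs(diff(tr$positions > 0.66)) > 0) + 1))
})

test_that("PMF serialization writes profile plus sidecar", {
  pmf <- pmf_polynomial(double_well_coefs(), kT = kT, support = c(0.2, 1.1))
  p <- tempfile(fileext = ".tsv")
  write_pmf(pmf, p)
  tab <- read.table(p, comment.char = "#")
  expect_equal(ncol(tab), 3)
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$kT, kT)
})
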