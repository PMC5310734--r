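test_that("promoter models validate generators and expose occupancy", {
  m <- rt_test_model()
  expect_equal(colSums(m$K), c(0, 0))
  occ <- stationary_occupancy(m)
  expect_equal(occ, c(0.4, 0.6), tolerance = 1e-12)   # k_on/(k_on+k_off) active
  reducible <- promoter_model(c(1, 2), c(1, 1), matrix(0, 2, 2))
  expect_error(stationary_occupancy(reducible), "reducible")
})

test_that("telegraph stationary drive is the scaled Beta", {
  m <- rt_test_model()
  d <- rt_stationary_density(m)
  expect_equal(density_mean(d), 8 * 0.6, tolerance = 1e-10)
  a <- 0.6; b <- 0.4
  expect_equal(density_var(d), 64 * a * b / ((a + b)^2 * (a + b + 1)),
               tolerance = 1e-9)
  expect_error(rt_stationary_density(refractory_test_model()), "unsupported")
})

test_that("refractory stationary density integrates to the chain occupancy", {
  m <- refractory_test_model()
  d <- refractory_stationary_density(m)
  expect_equal(txdrive:::density_total_mass(d), 1, tolerance = 1e-6)
  expect_equal(unname(d$state_masses), unname(stationary_occupancy(m)),
               tolerance = 1e-4)
  expect_equal(density_mean(d), 10 * stationary_occupancy(m)[1],
               tolerance = 1e-4)
  expect_error(refractory_stationary_density(rt_test_model()), "unsupported")
})

test_that("entrained sinusoidal population has the arcsine drive density", {
  mod <- sinusoidal_entrainment(10, 2 * pi / 24, lam = 0.3, r = pi)
  d <- re_phase_density(mod, 5)
  A <- 10 / (2 * 0.3)
  B <- (10 / 2) / sqrt(0.3^2 + (2 * pi / 24)^2)
  expect_equal(density_mean(d), A, tolerance = 1e-9)
  expect_equal(density_var(d), B^2 / 2, tolerance = 1e-9)  # arcsine variance
  expect_equal(d$support, c(A - B, A + B), tolerance = 1e-12)
})

test_that("synchronous entrainment degenerates to a point mass", {
  mod <- sinusoidal_entrainment(10, 2 * pi / 24, lam = 0.3, r = 0)
  d <- re_phase_density(mod, 5)
  expect_equal(nrow(d$atoms), 1L)
  pp <- txdrive:::re_chi_params(mod)
  expect_equal(d$atoms$location,
               pp$A + pp$B * sin(2 * pi / 24 * 5 - pp$psi))
})

test_that("restricted phase spread narrows the drive support", {
  mod <- sinusoidal_entrainment(10, 2 * pi / 24, lam = 0.3, r = pi / 3)
  d <- re_phase_density(mod, 5)
  # Monte-Carlo oracle on the same closed-form map
  set.seed(11)
  pp <- txdrive:::re_chi_params(mod)
  xs <- pp$A + pp$B * sin(2 * pi / 24 * 5 + runif(2e5, -pi / 3, pi / 3) - pp$psi)
  expect_equal(density_mean(d), mean(xs), tolerance = 5e-3)
  expect_lt(diff(d$support), 2 * pp$B)
})

test_that("degradation-entrained drive matches an independent ODE oracle", {
  mod <- sinusoidal_entrainment(6, 2 * pi / 10, r = pi,
                                target = "degradation", a = 1, b = 0.5)
  d <- re_degradation_density(mod, 3)
  phis <- seq(-pi, pi, length.out = 41)[-41]
  ref <- vapply(phis, function(phi) {
    f <- function(t, y, p) list(6 - (1 + 0.5 * sin(2 * pi / 10 * t + phi)) * y)
    unname(deSolve::ode(c(x = 0), seq(3 - 150, 3, 0.05), f, NULL,
                        rtol = 1e-10, atol = 1e-12)[3001, 2])
  }, numeric(1))
  expect_equal(density_mean(d), mean(ref), tolerance = 1e-3)
  expect_equal(d$support, range(ref), tolerance = 1e-2)
})

test_that("modulated telegraph density reduces to the scaled Beta at zero spread", {
  p0 <- mrt_params(8, 2 * pi / 24, 0.5, 0.4, 0.6, 0)
  d0 <- mrt_density(p0, 6)
  rho <- (8 / 2) * (1 + sin(2 * pi / 24 * 6))
  expect_equal(density_mean(d0), (rho / 0.5) * 0.4 / (0.4 + 0.6),
               tolerance = 1e-9)
  # widening the phase spread moves mass away from the zero-spread mean
  p1 <- mrt_params(8, 2 * pi / 24, 0.5, 0.4, 0.6, 0.5)
  d1 <- mrt_density(p1, 6)
  expect_equal(txdrive:::density_total_mass(d1), 1, tolerance = 1e-9)
  expect_lt(density_mean(d1), density_mean(d0))
  # very wide spread approaches the phase-uniform average strength
  p2 <- mrt_params(8, 2 * pi / 24, 0.5, 0.4, 0.6, 25)
  d2 <- mrt_density(p2, 6)
  expect_equal(density_mean(d2), (8 / 2) / 0.5 * 0.4, tolerance = 1e-3)
})
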