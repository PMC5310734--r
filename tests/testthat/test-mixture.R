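test_that("the closed-form telegraph pmf equals the quadrature mixture", {
  for (k_on in c(0.3, 1, 3)) for (k_off in c(0.4, 1.5)) {
    m <- rt_promoter(k_on, k_off, 8, 1)
    mix <- poisson_mixture(rt_stationary_density(m))
    pb <- poisson_beta_pmf(0:(length(mix$dist$pmf) - 1L), k_on, k_off, 8)
    exact <- copy_number_dist(pb / sum(pb), truncation_tail = 0)
    expect_lt(tv_distance(mix$dist, exact), 1e-9)
  }
})

test_that("the confluent hypergeometric series matches reference identities", {
  # 1F1(1, 2; z) = (e^z - 1)/z for z > 0
  for (z in c(0.1, 1, 10, 50))
    expect_equal(exp(txdrive:::log_kummer_series(1, 2, z)),
                 (exp(z) - 1) / z, tolerance = 1e-12)
  # 1F1(a, a; z) = e^z
  expect_equal(txdrive:::log_kummer_series(3.7, 3.7, 20), 20,
               tolerance = 1e-12)
})

test_that("poisson_beta_pmf stays normalised for bursty and large-scale regimes", {
  for (pars in list(c(0.05, 4, 60), c(2, 0.1, 150), c(5, 5, 400))) {
    p <- poisson_beta_pmf(0:2000, pars[1], pars[2], pars[3])
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-8)
  }
})

test_that("mixture moments obey the Poisson-mixture identities", {
  dens <- list(
    rt_stationary_density(rt_test_model()),
    re_phase_density(sinusoidal_entrainment(10, 2 * pi / 24, lam = 0.3,
                                            r = pi), 5),
    refractory_stationary_density(refractory_test_model())
  )
  for (d in dens) {
    mix <- poisson_mixture(d)
    mx <- density_mean(d); vx <- density_var(d)
    expect_equal(dist_mean(mix$dist), mx, tolerance = 1e-6)
    expect_equal(dist_var(mix$dist), mx + vx, tolerance = 1e-5)
    expect_gte(dist_var(mix$dist) / dist_mean(mix$dist), 1 - 1e-9)
  }
})

test_that("a single-cell time average reproduces the phase-mixture law", {
  mu <- rate_path_sinusoid(5, 5, 2 * pi / 10)
  lam <- rate_path_constant(1, kind = "degradation")
  chi <- solve_effective_drive(mu, lam, 5, seq(0, 60, 0.02))
  ta <- time_average_distribution(chi, 50, 60, periodic = TRUE)
  mod <- sinusoidal_entrainment(10, 2 * pi / 10, lam = 1, r = pi)
  mix <- poisson_mixture(re_phase_density(mod, 55))
  expect_lt(tv_distance(ta$dist, mix$dist), 1e-8)
})

test_that("histogram densities from sampled drives feed the mixture", {
  mod <- sinusoidal_entrainment(10, 2 * pi / 24, lam = 0.3, r = pi)
  xs <- sample_chi_snapshot(mod, t = 5, n_paths = 50000, seed = 8)
  mix_mc <- poisson_mixture(density_from_paths(xs))
  mix_exact <- poisson_mixture(re_phase_density(mod, 5))
  expect_lt(tv_distance(mix_mc$dist, mix_exact$dist), 0.01)
})
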