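test_that("finite-volume steady state reproduces the telegraph Beta law", {
  m <- rt_test_model()
  field <- fpk_steady_state(m, n_cells = 4096L)
  expect_equal(unname(field_state_masses(field)),
               unname(stationary_occupancy(m)), tolerance = 1e-6)
  mix_fv <- poisson_mixture(marginalize_density(field))
  pb <- poisson_beta_pmf(0:(length(mix_fv$dist$pmf) - 1L), 0.6, 0.4, 8)
  exact <- copy_number_dist(pb / sum(pb), truncation_tail = 0)
  expect_lt(tv_distance(mix_fv$dist, exact), 5e-4)
})

test_that("transient FPK evolution conserves mass and relaxes to the steady state", {
  m <- rt_promoter(0.8, 0.5, 6, 1)
  ss <- fpk_steady_state(m, n_cells = 1024L)
  per0 <- matrix(0, length(ss$x), 2)
  per0[which.min(abs(ss$x - 2)), 1] <- 1 / ss$dx
  init <- state_density_field(ss$x, per0, time = 0)
  out <- fpk_solve(m, init, c(0, 0.5, 2, 8))
  for (fld in out)
    expect_equal(sum(field_state_masses(fld)), 1, tolerance = 1e-9)
  tv_mid <- tv_distance(poisson_mixture(marginalize_density(out[[3]]))$dist,
                        poisson_mixture(marginalize_density(ss))$dist)
  tv_end <- tv_distance(poisson_mixture(marginalize_density(out[[4]]))$dist,
                        poisson_mixture(marginalize_density(ss))$dist)
  expect_lt(tv_end, tv_mid)         # monotone relaxation
  expect_lt(tv_end, 1e-3)
})

test_that("the grid must cover every drive fixed point", {
  m <- rt_test_model()
  x <- seq(0.025, 4.975, by = 0.05)  # upper end 5 < m/lam = 8
  per <- matrix(rep(c(0.1, 0.1), each = length(x)), ncol = 2)
  init <- state_density_field(x, per, time = 0)
  expect_error(fpk_solve(m, init, c(0, 1)), "fixed point")
})

test_that("marginalised fields are valid drive densities", {
  field <- fpk_steady_state(refractory_test_model(), n_cells = 512L)
  d <- marginalize_density(field)
  expect_s3_class(d, "drive_density")
  expect_equal(txdrive:::density_total_mass(d), 1, tolerance = 1e-9)
  expect_equal(density_mean(d),
               10 * stationary_occupancy(refractory_test_model())[1],
               tolerance = 5e-3)
})
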