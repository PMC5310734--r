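test_that("count paths are validated, queryable piecewise-constant records", {
  p <- count_path(c(0, 1.5, 2), c(3, 4, 3), t_end = 5)
  expect_equal(count_at(p, c(0, 1.4, 1.5, 4.9)), c(3, 3, 4, 3))
  expect_error(count_at(p, 6), "outside")
  expect_error(count_path(c(0, 1), c(0, 2), t_end = 2), "\\+-1")
  expect_silent(count_path(c(0, 1), c(0, 2), t_end = 2,
                           event_resolved = FALSE))
})

test_that("stochastic simulation is reproducible and event-resolved", {
  mu <- rate_path_sinusoid(5, 5, 2 * pi / 10)
  lam <- rate_path_constant(1, kind = "degradation")
  p1 <- ssa_timevarying(mu, lam, 0L, 20, seed = 9)
  p2 <- ssa_timevarying(mu, lam, 0L, 20, seed = 9)
  expect_identical(p1$times, p2$times)
  expect_identical(p1$counts, p2$counts)
  expect_true(all(abs(diff(p1$counts)) == 1))
  expect_true(all(p1$counts >= 0))
  p3 <- ssa_timevarying(mu, lam, 0L, 20, seed = 10)
  expect_false(identical(p1$times, p3$times))
})

test_that("a user-supplied thinning bound must dominate the transcription rate", {
  mu <- rate_path_sinusoid(5, 5, 2 * pi / 10)
  lam <- rate_path_constant(1, kind = "degradation")
  expect_error(ssa_timevarying(mu, lam, 0L, 20, seed = 1,
                               rate_upper_bound = 6), "below the supremum")
  p <- ssa_timevarying(mu, lam, 0L, 20, seed = 1, rate_upper_bound = 11)
  expect_s3_class(p, "count_path")
})

test_that("constant-rate simulation reproduces the Poisson law", {
  mu <- rate_path_constant(5)
  lam <- rate_path_constant(1, kind = "degradation")
  ns <- vapply(1:2500, function(i)
    count_at(ssa_timevarying(mu, lam, 0L, 10, seed = i), 10), numeric(1))
  emp <- empirical_dist(as.integer(ns))
  expect_lt(tv_distance(emp, longterm_pmf(5)), 0.04)
})

test_that("time-varying simulation matches the synchronous transient solution", {
  mu <- rate_path_sinusoid(5, 5, 2 * pi / 10)
  lam <- rate_path_constant(1, kind = "degradation")
  ns <- vapply(1:2500, function(i)
    count_at(ssa_timevarying(mu, lam, 0L, 4, seed = 5000 + i), 4), numeric(1))
  d <- synchronous_pmf(0L, mu, lam, 4)
  expect_lt(tv_distance(empirical_dist(as.integer(ns)), d), 0.04)
})

test_that("telegraph activity paths hit the stationary on-fraction", {
  tp <- telegraph_path(0.6, 0.4, 8000, seed = 3)
  tg <- seq(0, 8000, 0.5)
  expect_equal(mean(rate_at(tp, tg)), 0.6, tolerance = 0.05)
  tp2 <- telegraph_path(0.6, 0.4, 8000, seed = 3)
  expect_identical(tp$breaks, tp2$breaks)
})

test_that("drive snapshots recover stationary telegraph moments", {
  m <- rt_promoter(0.6, 0.4, 8, 1)
  xs <- sample_chi_snapshot(m, t = 25, n_paths = 1200, seed = 2)
  d <- rt_stationary_density(m)
  expect_equal(mean(xs), density_mean(d), tolerance = 0.05)
  expect_equal(stats::var(xs), density_var(d), tolerance = 0.1)
})

test_that("reference drive fixtures share period and mean level", {
  Tp <- 5; lev <- 4
  sin_d <- fixture_drives("sinusoid", Tp, lev)
  sq_d <- fixture_drives("square_wave", Tp, lev)
  tg <- seq(0, Tp, length.out = 10001)[-10001]
  expect_equal(mean(rate_at(sin_d, tg)), lev, tolerance = 1e-6)
  expect_equal(mean(rate_at(sq_d, tg)), lev, tolerance = 1e-3)
  expect_equal(rate_at(sin_d, 0), rate_at(sin_d, Tp))
  tel <- fixture_drives("telegraph", Tp, lev, seed = 6, t_end = 4000 * Tp)
  tg2 <- seq(0, 4000 * Tp, 0.9)
  expect_equal(mean(rate_at(tel, tg2)), lev, tolerance = 0.1)
})

test_that("Kuramoto populations synchronise as the coupling grows", {
  tg <- seq(0, 60, 0.05)
  pop_lo <- kuramoto_population(C = 60, K_coupling = 0.002, seed = 4)
  pop_hi <- kuramoto_population(C = 60, K_coupling = 1.5, seed = 4)
  r_lo <- kuramoto_simulate(pop_lo, tg)$r
  r_hi <- kuramoto_simulate(pop_hi, tg)$r
  expect_true(all(r_lo >= 0 & r_lo <= 1 + 1e-12))
  expect_gt(mean(tail(r_hi, 200)), 0.9)      # strong coupling locks phases
  expect_lt(mean(tail(r_lo, 200)), 0.6)
  expect_error(kuramoto_population(C = 10, K_coupling = 1, b = 0.5),
               "b")
})

test_that("Kuramoto drive paths feed exact mixtures of zero-start cells", {
  pop <- kuramoto_population(C = 80, K_coupling = 0.1, seed = 7)
  tg <- seq(0, 8, 0.05)
  sim <- kuramoto_simulate(pop, tg)
  cp <- kuramoto_chi_paths(pop, tg, sim = sim, chi0 = 0)
  expect_equal(dim(cp$chi), c(length(tg), 80))
  expect_true(all(cp$chi >= 0))
  dr <- kuramoto_drive_paths(pop, tg, sim = sim)
  # chi paths agree with solving the drive ODE on the tabulated rates
  chi_ref <- solve_effective_drive(dr$mu[[3]], dr$lam, 0, tg)
  expect_equal(cp$chi[length(tg), 3], chi_at(chi_ref, 8), tolerance = 1e-3)
})
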