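test_that("Stirling moment maps convert drive moments to copy-number moments", {
  expect_equal(txdrive:::stirling2_row(3), c(1, 3, 1))
  expect_equal(txdrive:::stirling2_row(5), c(1, 15, 25, 10, 1))
  # Poisson(x): all drive moments are x^k, so <N^2> = x + x^2
  expect_equal(factorial_moment_map(c(4, 16), 2), 4 + 16)
  # against a directly assembled mixture
  d <- rt_stationary_density(rt_test_model())
  m1 <- density_mean(d)
  m2 <- density_integral(d, function(x) x^2)
  m3 <- density_integral(d, function(x) x^3)
  mix <- poisson_mixture(d)
  n <- seq_along(mix$dist$pmf) - 1
  expect_equal(factorial_moment_map(c(m1, m2, m3), 3),
               sum(n^3 * mix$dist$pmf), tolerance = 1e-6)
  expect_error(factorial_moment_map(c(1, 2), 3), "need 3 drive moments")
})

test_that("copy-number variance splits into Poissonian and upstream parts", {
  v <- variance_decomposition(4, 2.5)
  expect_equal(unname(v), c(4, 2.5, 6.5))
  expect_error(variance_decomposition(4, -1), "non-negative")
})

test_that("ensemble Fano is 1 for Poisson and grows with upstream spread", {
  expect_equal(ensemble_fano(longterm_pmf(6)), 1, tolerance = 1e-9)
  mix <- poisson_mixture(rt_stationary_density(rt_test_model()))
  expect_gt(ensemble_fano(mix$dist), 1)
  set.seed(2)
  expect_equal(ensemble_fano(rpois(20000, 5)), 1, tolerance = 0.05)
  expect_error(ensemble_fano(rep(0L, 10)), "zero mean")
})

test_that("temporal Fano detects stationary windows on single trajectories", {
  p <- count_path(c(0, 1, 2, 3), c(2, 3, 2, 3), t_end = 4)
  expect_equal(temporal_fano(count_path(0, 5L, t_end = 10), c(0, 10)), 0)
  mom <- txdrive:::path_time_moments(p, 0, 4)
  expect_equal(mom[1], 2.5)            # half the time at 2, half at 3
  expect_equal(temporal_fano(p, c(0, 4)), 0.25 / 2.5)
  expect_error(temporal_fano(p, c(3, 3)), "empty")
  cf <- cumulative_fano(p, 0, c(2, 4))
  expect_equal(length(cf), 2L)
})

test_that("sinusoid fits recover exact generating parameters", {
  tt <- seq(0, 40, 0.05)
  fit <- fit_sinusoid(tt, 3 + 1.2 * sin(0.7 * tt + 0.4), 0.7)
  expect_equal(fit$offset, 3, tolerance = 1e-10)
  expect_equal(fit$amplitude, 1.2, tolerance = 1e-10)
  expect_equal(fit$phase, 0.4, tolerance = 1e-10)
  expect_equal(sinusoid_at(fit, 1.3), 3 + 1.2 * sin(0.7 * 1.3 + 0.4),
               tolerance = 1e-9)
})

test_that("the observed mean oscillation inverts to the upstream rate", {
  off <- 4; amp <- 2; w <- 0.5; lam <- 0.8; ph <- 0.9
  mu <- rate_path_sinusoid(off, amp, w, phase = ph)
  ms <- mean_ode_solve(mu, lam, off / lam, seq(0, 60, 0.1))
  sel <- ms$time > 30
  fit <- fit_sinusoid(ms$time[sel], ms$mean[sel], w)
  up <- infer_upstream_sinusoid(fit, lam)
  expect_equal(up$offset, off, tolerance = 1e-6)
  expect_equal(up$amplitude, amp, tolerance = 1e-6)
  expect_equal(sin(up$phase - ph), 0, tolerance = 1e-6)
  expect_equal(cos(up$phase - ph), 1, tolerance = 1e-6)
})

test_that("phase lags convert to time delays at the drive frequency", {
  expect_equal(phase_to_delay(pi, pi / 2), 2)
  expect_error(phase_to_delay(1, 0), "positive")
})

test_that("a deterministic shared drive keeps the population Poissonian", {
  mu <- rate_path_sinusoid(4, 2, 0.5)
  tg <- seq(0, 30, 0.1)
  lam <- 0.7
  chi <- solve_effective_drive(mu, rate_path_constant(lam, kind = "degradation"),
                               3, tg)
  mx <- rate_path(function(t) rate_at(mu, t) * chi_at(chi, t), c(0, 30))
  sm <- second_moment_ode_solve(mu, mx, lam, c(3, 9), tg)
  expect_lt(max(abs(sm$fano - 1)), 1e-5)
  expect_equal(sm$mean, chi_at(chi, tg), tolerance = 1e-8)
})
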