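test_that("rate paths validate their domain and sign", {
  p <- rate_path_constant(2, c(0, 10))
  expect_equal(rate_at(p, c(0, 5, 10)), c(2, 2, 2))
  expect_error(rate_at(p, 11), "outside")
  expect_error(rate_path_constant(-1), "value >= 0")
  expect_error(rate_path_sinusoid(1, 2, 1), "negative")
  expect_error(rate_at(rate_path(function(t) t - 5, c(0, 10)), 1),
               "negative or non-finite")
})

test_that("piecewise paths are right-continuous step functions", {
  p <- rate_path_piecewise(c(0, 2, 5), c(1, 4, 0), t_end = 10)
  expect_equal(rate_at(p, c(0, 1.99, 2, 4.99, 5, 10)),
               c(1, 1, 4, 4, 0, 0))
  expect_equal(txdrive:::rate_integral(p, 0, 10), 1 * 2 + 4 * 3 + 0 * 5)
  expect_equal(txdrive:::rate_integral(p, 1.5, 3), 0.5 * 1 + 1 * 4)
})

test_that("effective drive matches the steady-periodic closed form", {
  off <- 5; amp <- 5; w <- 2 * pi / 10; lam <- 1
  mu <- rate_path_sinusoid(off, amp, w)
  chi <- solve_effective_drive(mu, rate_path_constant(lam, kind = "degradation"),
                               0, seq(0, 80, 0.1))
  tq <- seq(60, 80, 0.7)   # past the transient
  expect_equal(chi_at(chi, tq), sinusoid_chi(tq, off, amp, w, 0, lam),
               tolerance = 1e-8)
})

test_that("piecewise rates are propagated exactly between breakpoints", {
  mu <- rate_path_piecewise(c(0, 2, 5), c(1, 4, 0), t_end = 10)
  lam <- rate_path_constant(0.5, kind = "degradation")
  chi <- solve_effective_drive(mu, lam, 0.5, seq(0, 10, 2.5))
  # manual two-segment propagation to t = 7
  v <- 1 / 0.5 + (0.5 - 1 / 0.5) * exp(-0.5 * 2)
  v <- 4 / 0.5 + (v - 4 / 0.5) * exp(-0.5 * 3)
  v <- 0 + (v - 0) * exp(-0.5 * 2)
  expect_equal(chi_at(chi, 7), v, tolerance = 1e-12)
  expect_true(chi$exact)
})

test_that("zero degradation accumulates the transcription integral", {
  mu <- rate_path_piecewise(c(0, 4), c(3, 0), t_end = 10)
  lam <- rate_path_constant(0, kind = "degradation")
  chi <- solve_effective_drive(mu, lam, 1, c(0, 10))
  expect_equal(chi_at(chi, 10), 1 + 3 * 4)
})

test_that("drive densities enforce normalisation and carry atoms", {
  expect_error(drive_density(x = 0:10, f = rep(1, 11)), "normalise")
  d <- delta_density(3.5)
  expect_equal(density_mean(d), 3.5)
  expect_equal(density_var(d), 0)
  x <- seq(0, 1, length.out = 201)
  # a pdf sampled on a finite grid carries O(h^2) trapezoid mass error,
  # so the normalisation check needs the matching tolerance
  d2 <- drive_density(x = x, f = stats::dbeta(x, 2, 3), normalize_tol = 1e-4)
  expect_equal(density_mean(d2), 2 / 5, tolerance = 1e-4)
})

test_that("sampled drive paths yield a normalised histogram density", {
  set.seed(4)
  s <- rbeta(5000, 2, 5) * 10
  d <- density_from_paths(s)
  expect_equal(txdrive:::density_total_mass(d), 1, tolerance = 1e-12)
  expect_equal(density_mean(d), mean(s), tolerance = 1e-2)
  expect_warning(density_from_paths(s[1:20]), "fewer than 100")
  dd <- density_from_paths(rep(2, 500))
  expect_equal(nrow(dd$atoms), 1L)
})

test_that("copy number distributions expose moments and TV distance", {
  d <- longterm_pmf(4)
  expect_equal(dist_mean(d), 4, tolerance = 1e-9)
  expect_equal(dist_var(d), 4, tolerance = 1e-8)
  expect_equal(tv_distance(d, d), 0)
  d2 <- longterm_pmf(5)
  expect_gt(tv_distance(d, d2), 0)
  expect_lt(tv_distance(d, d2), 1)
  # zero-padding: distributions of different truncation are comparable
  d3 <- copy_number_dist(c(d$pmf, 0, 0), truncation_tail = d$truncation_tail)
  expect_lt(tv_distance(d, d3), 1e-12)
})
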