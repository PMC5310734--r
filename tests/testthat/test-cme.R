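test_that("the truncated master equation recovers the constant-rate Poisson", {
  d <- cme_truncated_solve(list(m = 5, lam = 1))
  expect_lt(tv_distance(d, longterm_pmf(5)), 1e-10)
  # transient from n = 0: Poisson with the relaxing mean 5(1 - e^{-t})
  dt <- cme_truncated_solve(list(m = 5, lam = 1), t = 0.7)
  expect_lt(tv_distance(dt, longterm_pmf(5 * (1 - exp(-0.7)), time = 0.7)),
            1e-8)
})

test_that("the stationary telegraph master equation matches the Poisson-Beta law", {
  m <- rt_test_model()
  d <- cme_truncated_solve(m)
  pb <- poisson_beta_pmf(0:(length(d$pmf) - 1L), 0.6, 0.4, 8)
  expect_lt(tv_distance(d, copy_number_dist(pb / sum(pb),
                                            truncation_tail = 0)), 1e-9)
  # truncation is refused only when it cannot be enlarged
  expect_true(is.matrix(attr(d, "joint")))
  expect_equal(colSums(attr(d, "joint")), unname(stationary_occupancy(m)),
               tolerance = 1e-9)
})

test_that("burn-in from the silent inactive start converges monotonically", {
  bi <- burn_in_demo(rt_promoter(0.5, 0.5, 8, 1), seq(0, 12, 0.5))
  expect_true(all(diff(bi$tv) < 0))
  expect_lt(bi$tv[length(bi$tv)], 1e-3)
  expect_gt(bi$tv[1], 0.5)
  # late-time decay rate is set by the degradation rate (slowest mode)
  lt <- log(bi$tv)
  k <- length(lt)
  slope <- (lt[k] - lt[k - 4L]) / (bi$times[k] - bi$times[k - 4L])
  expect_equal(slope, -1, tolerance = 0.15)
})

test_that("the transient master equation tracks the synchronous Poisson solution", {
  mu <- rate_path_constant(5)
  lam <- rate_path_constant(1, kind = "degradation")
  d_cme <- cme_truncated_solve(list(m = 5, lam = 1), t = 1.3)
  d_sync <- synchronous_pmf(0L, mu, lam, 1.3)
  expect_lt(tv_distance(d_cme, d_sync), 1e-8)
})
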