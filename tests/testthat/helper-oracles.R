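# shared oracles for the test suite

# empirical pmf of integer samples as a copy_number_dist
empirical_dist <- function(samples, n_max = max(samples)) {
  p <- tabulate(samples + 1L, nbins = n_max + 1L) / length(samples)
  copy_number_dist(p, truncation_tail = max(0, 1 - sum(p)))
}

# closed-form steady-periodic drive under mu = off + amp sin(wt + ph),
# constant lam
sinusoid_chi <- function(t, off, amp, w, ph, lam)
  off / lam + amp / sqrt(lam^2 + w^2) * sin(w * t + ph - atan(w / lam))

rt_test_model <- function() rt_promoter(0.6, 0.4, 8, 1)

refractory_test_model <- function() refractory_promoter(0.7, 0.5, 0.3, 10, 1)
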