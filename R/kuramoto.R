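#' Kuramoto-coupled promoter population
#'
#' A population of C cells whose promoter strengths oscillate with phases
#' theta_i(t) governed by the globally coupled Kuramoto model
#' \deqn{\dot\theta_i = \omega_i + (K/C)\sum_j \sin(\theta_j - \theta_i),}
#' with intrinsic frequencies omega_i drawn from a Gaussian. The promoter
#' map is mu_i(t) = m (b + sin theta_i(t)), with b >= 1 so that the
#' transcription rate stays non-negative; degradation is a constant lam.
#' The coupling K tunes the degree of synchrony of the population.
#'
#' @param C number of cells (>= 2).
#' @param K_coupling non-negative coupling strength.
#' @param omega_mean,omega_sd mean and SD of the Gaussian intrinsic
#'   frequencies (defaults 1 and 0.1).
#' @param m promoter strength scale (default 5).
#' @param b baseline offset of the promoter map (default 1; must keep
#'   m (b + sin) non-negative, i.e. b >= 1).
#' @param lam degradation rate (default 1).
#' @param seed RNG seed for frequencies and initial phases.
#' @return An object of class `kuramoto_population`.
#' @export
kuramoto_population <- function(C, K_coupling, omega_mean = 1,
                                omega_sd = 0.1, m = 5, b = 1, lam = 1,
                                seed = 1L) {
  stopifnot(C >= 2, K_coupling >= 0, m > 0, lam > 0, omega_sd >= 0)
  if (b < 1) stop("promoter map m*(b + sin theta) would go negative: b < 1")
  structure(list(C = as.integer(C), K = K_coupling,
                 omega_mean = omega_mean, omega_sd = omega_sd,
                 m = m, b = b, lam = lam, seed = as.integer(seed)),
            class = "kuramoto_population")
}

#' Simulate the coupled phase dynamics
#'
#' Fixed-step RK4 integration of the mean-field form thetadot_i = omega_i +
#' K r sin(psi - theta_i) (equivalent to the all-to-all sum), step bounded
#' by 0.01 / max(|omega|, K). Reproducible by seed: identical seeds give
#' identical frequency draws, initial phases and trajectories.
#'
#' @param pop a `kuramoto_population`.
#' @param t_grid increasing output times (starting at the initial time).
#' @return List with `times`, `theta` (length(t_grid) x C matrix, phases
#'   mod 2pi), `r` (order parameter |mean e^{i theta}| at each time),
#'   `omega` (intrinsic frequencies).
#' @export
kuramoto_simulate <- function(pop, t_grid) {
  stopifnot(inherits(pop, "kuramoto_population"),
            !is.unsorted(t_grid, strictly = TRUE), length(t_grid) >= 2L)
  set.seed(pop$seed)
  omega <- stats::rnorm(pop$C, pop$omega_mean, pop$omega_sd)
  theta0 <- stats::runif(pop$C, 0, 2 * pi)
  h_max <- 0.01 / max(max(abs(omega)), pop$K, 1e-12)
  sim <- kuramoto_integrate(theta0, omega, pop$K, t_grid, h_max)
  sim$omega <- omega
  sim
}

kuramoto_rhs <- function(theta, omega, K) {
  z <- mean(exp(1i * theta))
  omega + K * Mod(z) * sin(Arg(z) - theta)
}

kuramoto_integrate <- function(theta0, omega, K, t_grid, h_max) {
  nt <- length(t_grid)
  C <- length(theta0)
  theta_out <- matrix(0, nt, C)
  r_out <- numeric(nt)
  theta <- theta0
  theta_out[1L, ] <- theta0 %% (2 * pi)
  r_out[1L] <- Mod(mean(exp(1i * theta0)))
  for (k in 2L:nt) {
    span <- t_grid[k] - t_grid[k - 1L]
    nsub <- max(1L, ceiling(span / h_max))
    h <- span / nsub
    for (s in seq_len(nsub)) {
      k1 <- kuramoto_rhs(theta, omega, K)
      k2 <- kuramoto_rhs(theta + h / 2 * k1, omega, K)
      k3 <- kuramoto_rhs(theta + h / 2 * k2, omega, K)
      k4 <- kuramoto_rhs(theta + h * k3, omega, K)
      theta <- theta + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    theta_out[k, ] <- theta %% (2 * pi)
    r_out[k] <- Mod(mean(exp(1i * theta)))
  }
  list(times = t_grid, theta = theta_out, r = r_out)
}

#' Per-cell transcription rate paths from the Kuramoto phases
#'
#' Builds mu_i(t) = m (b + sin theta_i(t)) as piecewise-linear `rate_path`s
#' on the simulation grid; degradation is the constant lam of the
#' population.
#'
#' @inheritParams kuramoto_simulate
#' @param sim optional result of [kuramoto_simulate()] on the same grid
#'   (recomputed if missing).
#' @return List with `mu` (list of C `rate_path`s), `lam` (constant
#'   `rate_path`), and `sim` (the phase simulation).
#' @export
kuramoto_drive_paths <- function(pop, t_grid, sim = NULL) {
  if (is.null(sim)) sim <- kuramoto_simulate(pop, t_grid)
  unwrapped <- sim$theta          # values mod 2pi; sin() is unaffected
  mu_vals <- pop$m * (pop$b + sin(unwrapped))
  if (any(mu_vals < -1e-9))
    stop("negative transcription rate: promoter offset b too small")
  mu_vals <- pmax(mu_vals, 0)
  dom <- range(t_grid)
  mu <- lapply(seq_len(pop$C), function(i) {
    f <- stats::approxfun(t_grid, mu_vals[, i], rule = 2L)
    rate_path(f, dom, "transcription")
  })
  list(mu = mu,
       lam = rate_path_constant(pop$lam, dom, "degradation"),
       sim = sim)
}

#' Effective-drive paths of a Kuramoto population
#'
#' Integrates chi_i alongside the phases with an exponential-integrator
#' step (mu held at its step midpoint), returning the C drive paths on the
#' output grid. `chi0` defaults to 0, matching trajectories started with
#' zero mRNA molecules, for which P(n, t) is exactly the Poisson mixture of
#' these chi values at every t.
#'
#' @inheritParams kuramoto_drive_paths
#' @param chi0 initial drive value for every cell (default 0).
#' @return List with `times`, `chi` (length(t_grid) x C matrix), `sim`.
#' @export
kuramoto_chi_paths <- function(pop, t_grid, sim = NULL, chi0 = 0) {
  if (is.null(sim)) sim <- kuramoto_simulate(pop, t_grid)
  mu_vals <- pop$m * (pop$b + sin(sim$theta))
  nt <- length(t_grid)
  chi <- matrix(0, nt, pop$C)
  chi[1L, ] <- chi0
  lam <- pop$lam
  for (k in 2L:nt) {
    h <- t_grid[k] - t_grid[k - 1L]
    mu_mid <- (mu_vals[k - 1L, ] + mu_vals[k, ]) / 2
    decay <- exp(-lam * h)
    chi[k, ] <- chi[k - 1L, ] * decay + mu_mid / lam * (1 - decay)
  }
  list(times = t_grid, chi = chi, sim = sim)
}
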