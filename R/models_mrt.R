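#' Modulated random telegraph (MRT) model
#'
#' A promoter that switches stochastically between on/off states (rates
#' k_on, k_off) while the strength of the on state is modulated by an
#' upstream sinusoid with a random phase per cell: the on-state
#' transcription rate is rho(t; phi) = (m/2)(1 + sin(omega t + phi)), with
#' phi ~ Normal(0, phase_sigma^2). A simple representation of, e.g.,
#' circadian modulation of a bursty promoter.
#'
#' @param m peak promoter strength.
#' @param omega angular frequency of the modulation.
#' @param lam degradation rate.
#' @param k_on,k_off telegraph switching rates.
#' @param phase_sigma standard deviation of the Gaussian phase spread
#'   (radians, >= 0).
#' @return An object of class `mrt_params`.
#' @export
mrt_params <- function(m, omega, lam, k_on, k_off, phase_sigma) {
  stopifnot(m > 0, omega > 0, lam > 0, k_on > 0, k_off > 0,
            phase_sigma >= 0)
  structure(list(m = m, omega = omega, lam = lam, k_on = k_on,
                 k_off = k_off, phase_sigma = phase_sigma),
            class = "mrt_params")
}

# modulation envelope of the on-state strength
mrt_rho <- function(params, t, phi)
  (params$m / 2) * (1 + sin(params$omega * t + phi))

#' Mixing density of the MRT model
#'
#' Conditional on the phase phi, the stationary drive is the telegraph
#' scaled Beta on [0, rho(t; phi)/lam] (the modulation is treated as slow
#' relative to the switching, so the phase-conditioned density keeps the
#' stationary Beta shape with a time-varying support). The phase is then
#' marginalised: by Gauss-Hermite quadrature for narrow phase spreads, or by
#' trapezoid over the wrapped-normal phase density on one period for wide
#' ones (the conditional density is 2pi-periodic in phi, which defeats
#' Gauss-Hermite once the Gaussian spans several periods).
#'
#' @param params an `mrt_params`.
#' @param t query time.
#' @param x_grid optional tabulation grid.
#' @param n_nodes quadrature nodes (default 64 Gauss-Hermite / 512 wrapped).
#' @return A `drive_density`.
#' @export
mrt_density <- function(params, t, x_grid = NULL, n_nodes = NULL) {
  stopifnot(inherits(params, "mrt_params"))
  alpha <- params$k_on / params$lam
  beta <- params$k_off / params$lam
  sig <- params$phase_sigma

  if (sig == 0) {
    rho <- mrt_rho(params, t, 0)
    return(scaled_beta_density(alpha, beta, rho / params$lam, t, x_grid))
  }
  if (sig <= 0.75) {
    if (is.null(n_nodes)) n_nodes <- 64L
    gh <- gauss_hermite(n_nodes)
    phis <- sqrt(2) * sig * gh$nodes
    wts <- gh$weights / sqrt(pi)
  } else {
    if (is.null(n_nodes)) n_nodes <- 512L
    phis <- seq(0, 2 * pi, length.out = n_nodes + 1L)[-(n_nodes + 1L)]
    wts <- wrapped_normal_pdf(phis, 0, sig) * (2 * pi / n_nodes)
    wts <- wts / sum(wts)
  }
  rhos <- mrt_rho(params, t, phis)
  scales <- pmax(rhos, 1e-12) / params$lam
  support <- c(0, params$m / params$lam)
  # cell-average representation through the conditional Beta cdfs: each
  # conditional support end is an interior integrable singularity of the
  # marginal pdf, but cell masses are exact, so the field sums to 1
  if (is.null(x_grid)) x_grid <- seq(0, support[2], length.out = 2049L)
  inner <- (x_grid[-1L] + x_grid[-length(x_grid)]) / 2
  brk <- c(support[1], inner, support[2])
  cellmass <- numeric(length(x_grid))
  for (q in seq_along(phis)) {
    Fq <- stats::pbeta(pmin(brk / scales[q], 1), alpha, beta)
    cellmass <- cellmass + wts[q] * diff(Fq)
  }
  dx <- diff(brk)
  drive_density(x = x_grid, f = cellmass / dx, support = support,
                time = t, w = dx, normalize_tol = 1e-9)
}

scaled_beta_density <- function(alpha, beta, scale, time, x_grid = NULL) {
  pdf <- function(x) stats::dbeta(x / scale, alpha, beta) / scale
  if (is.null(x_grid)) x_grid <- seq(0, scale, length.out = 513L)
  drive_density(x = x_grid, f = pmin(pdf(x_grid), 1e12), pdf = pdf,
                support = c(0, scale), time = time,
                exponents = c(alpha, beta))
}

# wrapped normal density on [0, 2pi)
wrapped_normal_pdf <- function(theta, mu, sigma) {
  kmax <- max(3L, ceiling(4 * sigma / (2 * pi)) + 1L)
  out <- numeric(length(theta))
  for (k in -kmax:kmax)
    out <- out + stats::dnorm(theta + 2 * pi * k, mu, sigma)
  out
}

# Golub-Welsch Gauss-Hermite nodes/weights (physicists' weight e^{-x^2})
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * e$vectors[1L, idx]^2)
}
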