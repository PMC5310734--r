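#' Stationary mixing density of the random telegraph promoter
#'
#' For the 2-state telegraph promoter (active rate m, common degradation
#' lam, switching rates k_on / k_off) the stationary effective drive is a
#' scaled Beta: X * lam / m ~ Beta(k_on/lam, k_off/lam) on [0, m/lam].
#'
#' @param model an RT `promoter_model` (see [rt_promoter()]).
#' @param x_grid optional tabulation grid.
#' @return A `drive_density` with the exact pdf.
#' @export
rt_stationary_density <- function(model, x_grid = NULL) {
  p <- as_rt_params(model)
  alpha <- p$k_on / p$lam
  beta <- p$k_off / p$lam
  scale <- p$m / p$lam
  pdf <- function(x) stats::dbeta(x / scale, alpha, beta) / scale
  if (is.null(x_grid)) x_grid <- seq(0, scale, length.out = 513L)
  drive_density(x = x_grid, f = pmin(pdf(x_grid), 1e12), pdf = pdf,
                support = c(0, scale), time = NA_real_,
                exponents = c(alpha, beta))
}

as_rt_params <- function(model) {
  if (inherits(model, "promoter_model")) {
    if (!(model$D == 2L && model$m_s[1] == 0 && model$m_s[2] > 0 &&
          abs(diff(model$lam_s)) < 1e-12))
      stop("unsupported model: expected 2-state telegraph form ",
           "(m_s = (0, m), common degradation rate)")
    list(k_on = model$K[2, 1], k_off = model$K[1, 2],
         m = model$m_s[2], lam = model$lam_s[1])
  } else stop("expected a promoter_model")
}

#' Stationary mixing density of the 3-state refractory promoter
#'
#' The promoter cycles s* (active) -> s1 -> s2 -> s* with rates k_*, k_1,
#' k_2; transcription at rate m only in s*, common degradation lam. In the
#' scaled variable y = lam x / m the stationary per-state densities satisfy
#' a linear ODE system with regular singular endpoints whose solution space
#' is two-dimensional; the two integration constants are determined
#' numerically by imposing the integral conditions int f_s dy = pi_s (the
#' chain's stationary occupancies). The basis solutions are integrated in
#' the logit variable tau = log(y/(1-y)), where the system is polynomial,
#' with Frobenius-series starts at y -> 0 and segment renormalisation
#' against overflow; quadrature states accumulate the integral conditions
#' alongside.
#'
#' The returned density carries its own quadrature rule: the nodes are the
#' logit-variable solve grid mapped back to x, the weights are trapezoid
#' weights in tau (where the integrand is smooth and decays exponentially)
#' with analytic power-law tails folded into the end weights. Integrals
#' against the density therefore avoid generic quadrature on the endpoint
#' singularities entirely.
#'
#' @param model a refractory `promoter_model` (see [refractory_promoter()]).
#' @param y_eps endpoint cut-off of the numerical solve (default 1e-8);
#'   beyond it the known power-law tails are used.
#' @return A `drive_density`; the per-state masses are stored in
#'   `$state_masses` (order s*, s1, s2).
#' @export
refractory_stationary_density <- function(model, y_eps = 1e-8) {
  if (!inherits(model, "promoter_model") || model$D != 3L ||
      is.null(model$kind) || model$kind != "refractory")
    stop("unsupported model: expected the 3-state cyclic refractory form")
  lam <- model$lam
  a_s <- model$k_star / lam
  a_1 <- model$k_1 / lam
  a_2 <- model$k_2 / lam
  if (abs(a_1 - a_2) < 1e-8) a_2 <- a_2 * (1 + 1e-7) + 1e-9  # degenerate pair
  scale <- model$m / lam
  pi_s <- stationary_occupancy(model)  # order (s*, s1, s2)

  basisA <- refractory_basis(a_s, a_1, a_2, y_eps, lead = "1")
  basisB <- refractory_basis(a_s, a_1, a_2, y_eps, lead = "2")

  # constants from the two inactive-state integral conditions
  Mmat <- cbind(c(basisA$I1, basisA$I2), c(basisB$I1, basisB$I2))
  cc <- solve(Mmat, c(pi_s[2], pi_s[3]))

  tau <- basisA$tau
  y <- 1 / (1 + exp(-tau))
  g1 <- cc[1] * basisA$g1 + cc[2] * basisB$g1
  g2 <- cc[1] * basisA$g2 + cc[2] * basisB$g2
  s <- pmax(g1 + g2, 0)

  # masses, including the analytic endpoint tails
  Istar <- cc[1] * basisA$Istar + cc[2] * basisB$Istar +
    s[length(s)] / a_s
  state_masses <- c(star = Istar, s1 = pi_s[2], s2 = pi_s[3])

  # marginal: f_*(y) + f_1(y) + f_2(y) = s(y) / (y (1 - y));
  # log s is interpolated linearly in tau (exact for the power-law tails)
  ls <- log(pmax(s, 1e-300))
  n <- length(tau)
  slope_lo <- (ls[2] - ls[1]) / (tau[2] - tau[1])
  slope_hi <- (ls[n] - ls[n - 1L]) / (tau[n] - tau[n - 1L])
  ls_fun <- stats::approxfun(tau, ls)
  pdf_y_raw <- function(yv) {
    yv <- pmin(pmax(yv, 1e-14), 1 - 1e-14)
    tv <- log(yv / (1 - yv))
    lsv <- numeric(length(tv))
    mid <- tv >= tau[1] & tv <= tau[n]
    lsv[mid] <- ls_fun(tv[mid])
    lsv[tv < tau[1]] <- ls[1] + slope_lo * (tv[tv < tau[1]] - tau[1])
    lsv[tv > tau[n]] <- ls[n] + slope_hi * (tv[tv > tau[n]] - tau[n])
    exp(lsv) / (yv * (1 - yv))
  }
  # Quadrature rule in tau, where s is smooth and decays exponentially:
  # trapezoid weights on the solve grid, plus analytic tails beyond the
  # cut-offs. The left tail keeps both Frobenius exponents (the subleading
  # one is fitted from the solution just inside the cut-off); the right
  # subleading correction is O(y_eps) and is dropped.
  pL <- min(a_1, a_2)
  pR <- a_s
  w_tau <- trapezoid_weights(tau)
  # Below the cut-off each basis is its pure Frobenius solution, so its
  # tail integral follows exactly from its value at the cut-off:
  # basis A scales as y^{a_1} (both components), basis B as y^{a_2} with an
  # O(y) first component.
  tail_l <- cc[1] * (basisA$g1[1] + basisA$g2[1]) / a_1 +
    cc[2] * (basisB$g2[1] / a_2 + basisB$g1[1] / (a_2 + 1))
  tail_l <- max(tail_l, 0)
  tail_r <- s[n] / a_s
  if (s[1] > 0) w_tau[1] <- w_tau[1] + tail_l / s[1]
  if (s[n] > 0) w_tau[n] <- w_tau[n] + tail_r / s[n]
  mass <- sum(w_tau * s)

  pdf <- function(x) pdf_y_raw(x / scale) / (mass * scale)
  x_nodes <- scale * y
  f_nodes <- s / (y * (1 - y)) / (mass * scale)
  w_nodes <- w_tau * scale * y * (1 - y)

  dens <- drive_density(x = x_nodes, f = f_nodes, w = w_nodes, pdf = pdf,
                        support = c(0, scale), time = NA_real_,
                        exponents = c(pL, pR), normalize_tol = 1e-6,
                        prefer_grid = TRUE)
  dens$state_masses <- state_masses / mass
  dens$occupancy <- pi_s
  dens
}

# one basis solution of the stationary refractory system, integrated in
# tau = log(y/(1-y)) with quadrature states; lead = which inactive-state
# exponent (y^{a_1} or y^{a_2}) the solution starts on
refractory_basis <- function(a_s, a_1, a_2, y_eps, lead) {
  tau0 <- log(y_eps / (1 - y_eps))
  tau1 <- -tau0
  if (lead == "1") {
    cA <- a_1 / (a_2 - a_1)
    state <- c(g1 = 1, g2 = cA, I1 = 1 / a_1, I2 = cA / a_1,
               Istar = (1 + cA) * y_eps / (a_1 + 1))
  } else {
    dB <- a_s / (a_1 - a_2 - 1)
    if (abs(a_1 - a_2 - 1) < 1e-8) dB <- a_s / (sign(a_1 - a_2 - 1 + 1e-15) * 1e-8)
    state <- c(g1 = dB * y_eps, g2 = 1, I1 = dB * y_eps / (a_2 + 1),
               I2 = 1 / a_2, Istar = (1 + dB * y_eps) * y_eps / (a_2 + 1))
  }
  rhs <- function(tt, st, parms) {
    y <- 1 / (1 + exp(-tt))
    g1 <- st[1]; g2 <- st[2]
    list(c((1 - y) * a_1 * g1 - a_s * y * (g1 + g2),
           (1 - y) * (a_2 * g2 - a_1 * g1),
           g1 * (1 - y),
           g2 * (1 - y),
           (g1 + g2) * y))
  }
  a_max <- max(a_s, a_1, a_2, 1)
  n_chunks <- max(1L, ceiling((tau1 - tau0) * a_max / 150))
  bounds <- seq(tau0, tau1, length.out = n_chunks + 1L)
  taus <- list(); g1s <- list(); g2s <- list()
  log_scale <- 0
  for (k in seq_len(n_chunks)) {
    npts <- max(24L, ceiling((bounds[k + 1L] - bounds[k]) * 160))
    grid <- seq(bounds[k], bounds[k + 1L], length.out = npts)
    sol <- deSolve::lsoda(y = state, times = grid, func = rhs, parms = NULL,
                          rtol = 1e-11, atol = 1e-300)
    taus[[k]] <- grid[-1L]
    g1s[[k]] <- cbind(sol[-1L, 2L], log_scale)
    g2s[[k]] <- cbind(sol[-1L, 3L], log_scale)
    state <- sol[nrow(sol), -1L]
    sc <- max(abs(state[1:2]))
    if (sc > 1e100) {
      state <- state / sc
      log_scale <- log_scale + log(sc)
    }
  }
  tau <- c(tau0, unlist(taus))
  final_log <- log_scale
  fix <- function(lst, first) {
    v <- do.call(rbind, lst)
    c(first, v[, 1L] * exp(v[, 2L] - final_log))
  }
  # initial point rescaled to the final normalisation
  g1_start <- if (lead == "1") 1 else a_s / (a_1 - a_2 - 1) * y_eps
  g2_start <- if (lead == "1") a_1 / (a_2 - a_1) else 1
  g1 <- fix(g1s, g1_start * exp(-final_log))
  g2 <- fix(g2s, g2_start * exp(-final_log))
  list(tau = tau, g1 = g1, g2 = g2,
       I1 = unname(state[3]), I2 = unname(state[4]),
       Istar = unname(state[5]))
}
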