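#' Random entrainment (RE) to an upstream sinusoidal signal
#'
#' Describes a cell population entrained to a rhythmic upstream signal with a
#' random, static phase offset per cell. The entrainment can act on the
#' transcription rate, mu(t) = (m/2)(1 + sin(omega t + Phi)) with constant
#' degradation lam, or on the degradation rate, lam(t) = a + b sin(omega t +
#' Phi) with constant transcription m. The phase Phi is uniform on [-r, r]:
#' r = 0 is a perfectly synchronous population, r = pi a fully asynchronous
#' one.
#'
#' @param m peak transcription scale (rate units).
#' @param omega angular frequency of the entraining signal.
#' @param lam constant degradation rate (transcription target).
#' @param r phase spread, in [0, pi].
#' @param target `"transcription"` or `"degradation"`.
#' @param a,b mean and modulation amplitude of the degradation rate
#'   (degradation target only); requires a > b >= 0.
#' @return An object of class `sinusoidal_entrainment`.
#' @export
sinusoidal_entrainment <- function(m, omega, lam = NULL, r,
                                   target = "transcription",
                                   a = NULL, b = NULL) {
  target <- match.arg(target, c("transcription", "degradation"))
  stopifnot(m > 0, omega > 0, r >= 0, r <= pi)
  if (target == "transcription") {
    stopifnot(!is.null(lam), lam > 0)
  } else {
    stopifnot(!is.null(a), !is.null(b), a > 0, b >= 0)
    if (b >= a) stop("degradation rate would touch zero: require b < a")
  }
  structure(list(m = m, omega = omega, lam = lam, r = r, target = target,
                 a = a, b = b),
            class = "sinusoidal_entrainment")
}

# steady-periodic response of dchi/dt = mu - lam*chi to
# mu = (m/2)(1 + sin(omega t + phi)):
#   chi(t) = m/(2 lam) + (m/2)/sqrt(lam^2+omega^2) * sin(omega t + phi - psi)
# with lag psi = arctan(omega/lam).
re_chi_params <- function(model) {
  list(A = model$m / (2 * model$lam),
       B = (model$m / 2) / sqrt(model$lam^2 + model$omega^2),
       psi = atan(model$omega / model$lam))
}

# number of phases phi in [-r, r] with sin(z0 + phi) = u, z0 = omega*t - psi
sine_branch_count <- function(u, z0, r) {
  cnt <- integer(length(u))
  ok <- abs(u) < 1
  if (!any(ok)) return(cnt)
  as_u <- asin(u[ok])
  for (c_base in list(as_u, pi - as_u)) {
    cc <- c_base - z0
    k_lo <- ceiling((-r - cc) / (2 * pi) - 1e-12)
    k_hi <- floor((r - cc) / (2 * pi) + 1e-12)
    cnt[ok] <- cnt[ok] + pmax(0L, as.integer(k_hi - k_lo + 1L))
  }
  cnt
}

#' Mixing density of the RE transcription model
#'
#' The effective drive at time t is X_t = A + B sin(omega t + Phi - psi)
#' with Phi uniform on [-r, r]. Its density is obtained by inverting the
#' sine: each preimage branch contributes 1 / (2 r sqrt(B^2 - (x-A)^2)), and
#' the number of branches l(x, t) is counted explicitly. For r = 0 the
#' density degenerates to a point mass at the synchronous drive value.
#'
#' @param model a `sinusoidal_entrainment` with transcription target.
#' @param t query time.
#' @param x_grid grid on which density values are tabulated (the returned
#'   object also carries the exact pdf for quadrature).
#' @return A `drive_density`.
#' @export
re_phase_density <- function(model, t, x_grid = NULL) {
  stopifnot(inherits(model, "sinusoidal_entrainment"),
            model$target == "transcription")
  pp <- re_chi_params(model)
  z0 <- model$omega * t - pp$psi
  r <- model$r
  if (r <= 0)
    return(delta_density(pp$A + pp$B * sin(z0), time = t))

  # actual support of x over phi in [-r, r]
  zr <- c(z0 - r, z0 + r)
  smax <- if (contains_angle(zr, pi / 2)) 1 else max(sin(zr))
  smin <- if (contains_angle(zr, -pi / 2)) -1 else min(sin(zr))
  support <- pp$A + pp$B * c(smin, smax)

  pdf <- function(x) {
    u <- (x - pp$A) / pp$B
    l <- sine_branch_count(u, z0, r)
    d <- numeric(length(x))
    ok <- l > 0 & abs(u) < 1
    d[ok] <- l[ok] / (2 * r * pp$B * sqrt(1 - u[ok]^2))
    d
  }
  if (is.null(x_grid))
    x_grid <- seq(support[1], support[2], length.out = 513L)
  f <- pmin(pdf(x_grid), 1e12)
  # fully asynchronous phases give the pure arcsine density: square-root
  # endpoint singularities and a constant branch count, so integrals can
  # use the exact Gauss-Jacobi endpoint weights; for r < pi the branch
  # count jumps inside the support and adaptive quadrature is used instead
  expo <- if (r >= pi - 1e-12) c(1 / 2, 1 / 2) else NULL
  drive_density(x = x_grid, f = f, pdf = pdf, support = support, time = t,
                exponents = expo, normalize_tol = 1e-5)
}

# does the arc [z[1], z[2]] contain angle `a` modulo 2*pi?
contains_angle <- function(z, a) {
  k_lo <- ceiling((z[1] - a) / (2 * pi) - 1e-12)
  k_hi <- floor((z[2] - a) / (2 * pi) + 1e-12)
  k_hi >= k_lo
}

#' Mixing density of the RE degradation model
#'
#' Transcription is constant m while the degradation rate is sinusoidally
#' modulated, lam(t) = a + b sin(omega t + Phi), Phi uniform on [-r, r]. The
#' steady-periodic effective drive chi(t; phi) is computed numerically on a
#' dense phase grid (one vectorised fixed-step integration over a period,
#' using the exact one-period multiplier exp(-aT)), and the density follows
#' by the change of variables from the uniform phase through the monotone
#' segments of the map phi -> chi.
#'
#' @inheritParams re_phase_density
#' @param n_phase phase-grid resolution (default 4097).
#' @return A `drive_density`.
#' @export
re_degradation_density <- function(model, t, x_grid = NULL,
                                   n_phase = 4097L) {
  stopifnot(inherits(model, "sinusoidal_entrainment"),
            model$target == "degradation")
  r <- model$r
  period <- 2 * pi / model$omega
  phis <- if (r > 0) seq(-r, r, length.out = n_phase) else 0

  # chi at absolute time t of the periodic solution: integrate one period
  # with zero initial condition (vectorised RK4 across phases), then apply
  # the exact fixed point chi = H / (1 - G), G = exp(-a T).
  nstep <- 4096L
  h <- period / nstep
  lam_f <- function(s, phi) model$a + model$b * sin(model$omega * s + phi)
  chi <- numeric(length(phis))
  tt <- t - period
  for (i in seq_len(nstep)) {
    k1 <- model$m - lam_f(tt, phis) * chi
    k2 <- model$m - lam_f(tt + h / 2, phis) * (chi + h / 2 * k1)
    k3 <- model$m - lam_f(tt + h / 2, phis) * (chi + h / 2 * k2)
    k4 <- model$m - lam_f(tt + h, phis) * (chi + h * k3)
    chi <- chi + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tt <- tt + h
  }
  G <- exp(-model$a * period)
  chi <- chi / (1 - G)

  if (r <= 0 || diff(range(chi)) < 1e-10)
    return(delta_density(mean(chi), time = t))
  density_from_phase_map(phis, chi, t, x_grid)
}

# density of x = map(phi), phi ~ Uniform over the (sorted, uniform) phi
# grid; inversion through monotone segments of the map
density_from_phase_map <- function(phis, xval, time, x_grid = NULL) {
  half_width <- (phis[length(phis)] - phis[1]) / 2
  dphi <- phis[2] - phis[1]
  dx <- c(xval[2] - xval[1], (xval[-(1:2)] - xval[1:(length(xval) - 2L)]) / 2,
          xval[length(xval)] - xval[length(xval) - 1L]) / dphi
  sgn <- sign(dx); sgn[sgn == 0] <- 1
  seg_id <- cumsum(c(1L, abs(diff(sgn)) > 0))
  segs <- split(seq_along(phis), seg_id)
  interp <- lapply(segs, function(idx) {
    if (length(idx) < 2L) return(NULL)
    xs <- xval[idx]; slopes <- abs(dx[idx])
    o <- order(xs)
    list(rng = range(xs),
         slope_of_x = stats::approxfun(xs[o], pmax(slopes[o], 1e-300),
                                       rule = 2L))
  })
  interp <- Filter(Negate(is.null), interp)
  pdf_raw <- function(x) {
    d <- numeric(length(x))
    for (sg in interp) {
      ok <- x >= sg$rng[1] & x <= sg$rng[2]
      if (any(ok))
        d[ok] <- d[ok] + 1 / (2 * half_width * sg$slope_of_x(x[ok]))
    }
    d
  }
  support <- range(xval)
  # the map extrema sit at the support ends, so the density carries
  # inverse-square-root endpoint singularities: normalise with the same
  # Gauss-Jacobi rule that density_integral will use, which removes the
  # O(h^2) discretisation error of the finite-difference slopes
  q <- gauss_jacobi(240L, alpha = -1 / 2, beta = -1 / 2)
  xq <- support[1] + diff(support) * (1 + q$nodes) / 2
  smooth <- pdf_raw(xq) * sqrt((xq - support[1]) * (support[2] - xq))
  mass <- sum(q$weights * smooth)
  pdf <- function(x) pdf_raw(x) / mass
  if (is.null(x_grid))
    x_grid <- seq(support[1], support[2], length.out = 513L)
  drive_density(x = x_grid, f = pmin(pdf(x_grid), 1e12), pdf = pdf,
                support = support, time = time,
                exponents = c(1 / 2, 1 / 2), normalize_tol = 1e-6)
}
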