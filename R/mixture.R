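#' Assemble the Poisson mixture distribution
#'
#' The central solution form: P(n, t) = sum_atoms w Poisson(n; x_atom) +
#' integral Poisson(n; x) f_X(x, t) dx. The continuous part is evaluated by
#' adaptive quadrature on the density's pdf (robust to integrable endpoint
#' singularities of Beta- and arcsine-type mixing densities), or by the
#' stored grid weights for purely tabulated densities.
#'
#' @param density a `drive_density` (normalised).
#' @param n_max truncation; auto-extended until the tail tolerance is met.
#' @param tail_tol truncation tail tolerance (default 1e-10).
#' @return A `mixture_result`: list with `dist` (a `copy_number_dist`),
#'   `source` tag, and `diagnostics` (mean mismatch of the assembled pmf
#'   against the mixing density, relative).
#' @export
poisson_mixture <- function(density, n_max = NULL, tail_tol = 1e-10) {
  stopifnot(inherits(density, "drive_density"))
  mx <- density_mean(density)
  hi <- if (all(is.finite(density$support))) density$support[2] else
    mx + 10 * sqrt(mx + 1)
  if (is.null(n_max)) n_max <- default_nmax(hi)
  repeat {
    pmf <- vapply(0:n_max, function(n)
      density_integral(density, function(x) stats::dpois(n, x),
                       rel.tol = 1e-9, abs.tol = 1e-12),
      numeric(1))
    tail <- max(0, 1 - sum(pmf))
    if (tail < tail_tol || n_max > 1e5) break
    n_max <- 2L * n_max + 10L
  }
  dist <- copy_number_dist(pmin(pmax(pmf, 0), 1), time = density$time,
                           truncation_tail = tail)
  mean_err <- abs(dist_mean(dist) - mx) / max(mx, 1e-12)
  structure(list(dist = dist, source = "quadrature",
                 diagnostics = c(mean_rel_err = mean_err)),
            class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat(sprintf("<mixture_result> source=%s, mean=%.4g, Fano=%.4g\n",
              x$source, dist_mean(x$dist), dist_var(x$dist) / dist_mean(x$dist)))
  invisible(x)
}

#' Closed-form stationary pmf of the random telegraph model
#'
#' The Poisson-Beta mixture: for X/scale ~ Beta(alpha, beta) the stationary
#' copy-number pmf is
#' \deqn{P(n) = \frac{scale^n}{n!}\frac{B(\alpha+n,\beta)}{B(\alpha,\beta)}
#'   \,{}_1F_1(\alpha+n, \alpha+\beta+n; -scale),}
#' evaluated in log space after the Kummer transformation
#' 1F1(a, b; -z) = exp(-z) 1F1(b-a, b; z), whose series has all-positive
#' terms (no cancellation, overflow-safe for large scale).
#'
#' @param n integer vector of copy numbers.
#' @param alpha,beta_param Beta shape parameters (k_on/lam, k_off/lam).
#' @param scale upper end of the drive support (m/lam).
#' @return Probabilities P(n).
#' @export
poisson_beta_pmf <- function(n, alpha, beta_param, scale) {
  if (alpha <= 0 || beta_param <= 0 || scale <= 0)
    stop("poisson_beta_pmf parameters must be positive")
  stopifnot(all(n >= 0), all(n == round(n)))
  vapply(n, function(nn) {
    lg <- nn * log(scale) - lgamma(nn + 1) +
      lbeta(alpha + nn, beta_param) - lbeta(alpha, beta_param) -
      scale + log_kummer_series(beta_param, alpha + beta_param + nn, scale)
    exp(lg)
  }, numeric(1))
}

# log 1F1(a, b; z) for a, b, z > 0 by the all-positive series, in log space
log_kummer_series <- function(a, b, z, max_terms = 100000L) {
  lterm <- 0
  lsum <- 0
  k <- 0L
  repeat {
    lterm <- lterm + log(a + k) - log(b + k) + log(z) - log(k + 1)
    lsum <- lsum + log1p(exp(lterm - lsum))
    k <- k + 1L
    if (lterm < lsum + log(.Machine$double.eps) - 4 || k >= max_terms) break
  }
  lsum
}

#' Ergodic time-averaged copy-number distribution
#'
#' (1/(t2-t1)) int Poisson(n; chi(t)) dt along one cell's effective-drive
#' path: under stationarity and ergodicity this estimates the stationary
#' population distribution from a single-cell trajectory. The integral is
#' evaluated by composite quadrature on a dense time grid (refined at the
#' breakpoints of piecewise-exact drives).
#'
#' @param chi an `effective_drive`.
#' @param t_start,t_end averaging window.
#' @param n_max truncation (auto-chosen from the drive's maximum).
#' @param n_nodes minimum number of quadrature nodes (default 4001).
#' @param periodic if `TRUE`, the window is one period of a periodic drive
#'   and the result is flagged as exact-period averaging.
#' @return A `mixture_result` with source `"time_average"`.
#' @export
time_average_distribution <- function(chi, t_start, t_end, n_max = NULL,
                                      n_nodes = 4001L, periodic = FALSE) {
  stopifnot(inherits(chi, "effective_drive"), t_end > t_start)
  tg <- seq(t_start, t_end, length.out = n_nodes)
  if (chi$exact && !is.null(chi$mu) && isTRUE(chi$mu$piecewise)) {
    bp <- chi$mu$breaks
    tg <- sort(unique(c(tg, bp[bp > t_start & bp < t_end])))
  }
  vals <- chi_at(chi, tg)
  w <- trapezoid_weights(tg)
  w <- w / sum(w)
  if (is.null(n_max)) n_max <- default_nmax(max(vals))
  pmf <- vapply(0:n_max, function(n) sum(w * stats::dpois(n, vals)),
                numeric(1))
  tail <- max(0, 1 - sum(pmf))
  dist <- copy_number_dist(pmf, time = NA_real_, truncation_tail = tail)
  mean_err <- abs(dist_mean(dist) - sum(w * vals)) / max(sum(w * vals), 1e-12)
  structure(list(dist = dist, source = "time_average",
                 diagnostics = c(mean_rel_err = mean_err),
                 periodic = periodic),
            class = "mixture_result")
}

#' Estimate a mixing density from sampled drive values
#'
#' Histogram estimator (Freedman-Diaconis bin width by default) of f_X from
#' independent samples of the effective drive at a fixed time -- the fast
#' sampling scheme: simulate cheap ODE paths of X instead of full
#' event-level trajectories of N, then mix.
#'
#' @param chi_samples numeric vector of sampled drive values (>= 100 for a
#'   warning-free estimate).
#' @param x_grid optional evaluation grid.
#' @param bins optional bin count (default Freedman-Diaconis).
#' @param time optional time stamp.
#' @return A `drive_density`.
#' @export
density_from_paths <- function(chi_samples, x_grid = NULL, bins = NULL,
                               time = NA_real_) {
  stopifnot(is.numeric(chi_samples), all(is.finite(chi_samples)),
            all(chi_samples >= 0))
  n <- length(chi_samples)
  if (n < 100L)
    warning("fewer than 100 drive samples; density estimate will be noisy")
  rng <- range(chi_samples)
  if (diff(rng) < 1e-12)
    return(delta_density(mean(chi_samples), time = time))
  if (!is.null(x_grid)) {
    # x_grid taken as bin midpoints; edge bins clipped at the sample range
    inner <- (x_grid[-1L] + x_grid[-length(x_grid)]) / 2
    brk <- c(min(rng[1], x_grid[1]), inner, max(rng[2], x_grid[length(x_grid)]))
  } else {
    if (is.null(bins)) {
      iqr <- stats::IQR(chi_samples)
      h <- if (iqr > 0) 2 * iqr / n^(1 / 3) else diff(rng) / ceiling(sqrt(n))
      bins <- max(10L, min(2000L, ceiling(diff(rng) / h)))
    }
    brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  }
  nb <- length(brk) - 1L
  cnt <- tabulate(pmin(pmax(findInterval(chi_samples, brk,
                                         rightmost.closed = TRUE), 1L), nb),
                  nbins = nb)
  dens <- cnt / (n * diff(brk))
  mids <- (brk[-1L] + brk[-length(brk)]) / 2
  # bin-integral (midpoint) representation: exact unit mass by construction
  drive_density(x = mids, f = dens, support = rng, time = time,
                w = diff(brk), normalize_tol = 1e-9)
}
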