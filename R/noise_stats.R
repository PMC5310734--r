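#' Moment maps between the drive and the copy number
#'
#' For a Poisson mixture, the raw moments of the copy number N follow from
#' the raw moments of the drive X through Stirling numbers of the second
#' kind: <N^j> = sum_k S(j, k) <X^k>.
#'
#' @param drive_moments numeric vector of raw drive moments, element k is
#'   <X^k> (length >= j).
#' @param j moment order (>= 1).
#' @return The raw moment <N^j>.
#' @export
factorial_moment_map <- function(drive_moments, j) {
  if (j < 1 || j != round(j)) stop("moment order j must be a positive integer")
  if (length(drive_moments) < j)
    stop(sprintf("need %d drive moments for order %d, got %d",
                 j, j, length(drive_moments)))
  S <- stirling2_row(j)
  sum(S[seq_len(j)] * drive_moments[seq_len(j)])
}

# Stirling numbers of the second kind S(j, k), k = 1..j, exact integer
# recurrence S(j,k) = k S(j-1,k) + S(j-1,k-1)
stirling2_row <- function(j) {
  S <- 1
  if (j == 1L) return(S)
  for (m in 2:j) S <- c(S * seq_along(S), 0)[1:m] + c(0, S)
  S
}

#' Decompose the copy-number variance into noise sources
#'
#' Var(N) = <X> + Var(X): a Poissonian downstream part equal to the mean
#' drive, plus the upstream part equal to the drive variance.
#'
#' @param drive_mean,drive_var mean and variance of the drive at the query
#'   time.
#' @return Named vector `(poisson_part, upstream_part, total)`.
#' @export
variance_decomposition <- function(drive_mean, drive_var) {
  if (drive_var < 0) stop("drive variance must be non-negative")
  c(poisson_part = drive_mean, upstream_part = drive_var,
    total = drive_mean + drive_var)
}

#' Time-dependent ensemble moments from the drive moments
#'
#' Solves d<N>/dt = <M_t> - lambda <N> for the ensemble mean (the same
#' linear ODE as the effective drive), and optionally the second-moment
#' equation d<X^2>/dt = 2 <M_t X_t> - 2 lambda <X^2>, mapping to <N^2> via
#' the Stirling relation <N^2> = <X> + <X^2>.
#'
#' @param mu_mean `rate_path` of the ensemble-mean transcription rate.
#' @param lam constant degradation rate.
#' @param init_mean initial ensemble mean.
#' @param t_grid output times.
#' @return A `moment_series`: data frame with `time`, `mean` (and after
#'   [second_moment_ode_solve()] also `second_moment`, `variance`, `fano`).
#' @export
mean_ode_solve <- function(mu_mean, lam, init_mean, t_grid) {
  stopifnot(lam > 0)
  chi <- solve_effective_drive(mu_mean,
                               rate_path_constant(lam, mu_mean$domain,
                                                  "degradation"),
                               init_mean, t_grid)
  structure(data.frame(time = t_grid, mean = chi_at(chi, t_grid)),
            class = c("moment_series", "data.frame"),
            provenance = "analytic")
}

#' @rdname mean_ode_solve
#' @param cross_moment_MX `rate_path` carrying the drive cross moment
#'   <M_t X_t> (supplied by the drive model).
#' @param init `(mean, second moment of X)` at `t_grid[1]`.
#' @export
second_moment_ode_solve <- function(mu_mean, cross_moment_MX, lam, init,
                                    t_grid) {
  stopifnot(lam > 0, length(init) == 2L)
  ms <- mean_ode_solve(mu_mean, lam, init[1], t_grid)
  # d<X^2>/dt = 2<MX> - 2 lam <X^2>: same linear form, doubled rates
  x2 <- solve_effective_drive(
    rate_path(function(t) 2 * rate_at(cross_moment_MX, t),
              cross_moment_MX$domain, "transcription"),
    rate_path_constant(2 * lam, cross_moment_MX$domain, "degradation"),
    init[2], t_grid)
  x2v <- chi_at(x2, t_grid)
  n2 <- ms$mean + x2v                 # <N^2> = <X> + <X^2>
  ms$second_moment <- n2
  ms$variance <- pmax(n2 - ms$mean^2, 0)
  ms$fano <- ifelse(ms$mean > 0, ms$variance / ms$mean, NA_real_)
  ms
}

#' Ensemble Fano factor
#'
#' Variance over mean of the copy number across the population at a fixed
#' time: 1 for a Poisson (perfectly synchronous) population, > 1 whenever
#' the upstream drive varies across cells. Accepts either a pmf or a raw
#' snapshot of counts (unbiased sample variance).
#'
#' @param snapshot a `copy_number_dist` or an integer vector of counts.
#' @return The Fano factor.
#' @export
ensemble_fano <- function(snapshot) {
  if (inherits(snapshot, "copy_number_dist")) {
    m <- dist_mean(snapshot)
    if (m <= 0) stop("Fano factor undefined: zero mean")
    return(dist_var(snapshot) / m)
  }
  x <- as.numeric(snapshot)
  m <- mean(x)
  if (m <= 0) stop("Fano factor undefined: zero mean")
  stats::var(x) / m
}

#' Temporal Fano factor over a time window
#'
#' Time-weighted variance over time-weighted mean of a single-cell
#' trajectory on the window (t1, t2): close to 1 over windows where the
#' trajectory is stationary (locally Poisson), and above 1 across promoter
#' switching transients -- a detector of windows of stationarity.
#'
#' @param path a `count_path`.
#' @param window length-2 numeric `(t1, t2)` inside the path span.
#' @return The temporal Fano factor (0 for a constant path).
#' @export
temporal_fano <- function(path, window) {
  stopifnot(inherits(path, "count_path"), length(window) == 2L)
  t1 <- window[1]; t2 <- window[2]
  if (!(t2 > t1)) stop("empty time window")
  if (t1 < path$times[1] - 1e-9 || t2 > path$t_end + 1e-9)
    stop("window outside the path span")
  mom <- path_time_moments(path, t1, t2)
  if (mom[1] <= 0) return(0)
  (mom[2] - mom[1]^2) / mom[1]
}

# time-weighted first two moments of a piecewise-constant count path
path_time_moments <- function(path, t1, t2) {
  tt <- path$times
  knots <- sort(unique(c(t1, t2, tt[tt > t1 & tt < t2])))
  lev <- path$counts[pmax(1L, findInterval(knots[-length(knots)], tt))]
  w <- diff(knots) / (t2 - t1)
  c(sum(w * lev), sum(w * lev^2))
}

#' Cumulative temporal Fano factor
#'
#' [temporal_fano()] over the growing windows (t1, t) for each t in
#' `t_grid`: its step-like increases align with promoter switching events.
#'
#' @param path a `count_path`.
#' @param t1 window start.
#' @param t_grid increasing end-times (> t1).
#' @return Numeric vector of cumulative Fano values.
#' @export
cumulative_fano <- function(path, t1, t_grid) {
  stopifnot(all(t_grid > t1))
  vapply(t_grid, function(t2) temporal_fano(path, c(t1, t2)), numeric(1))
}

#' Fitted sinusoid of a population-averaged expression time course
#'
#' `offset + amplitude * sin(omega t + phase)`, with omega known and fixed
#' (set by the upstream drive); the fit is linear least squares on the
#' sin/cos basis.
#'
#' @param times,values observed time course of the ensemble mean.
#' @param omega known angular frequency.
#' @return A `fitted_sinusoid` (fields `offset`, `amplitude`, `omega`,
#'   `phase`).
#' @export
fit_sinusoid <- function(times, values, omega) {
  stopifnot(omega > 0, length(times) == length(values), length(times) >= 3L)
  X <- cbind(1, sin(omega * times), cos(omega * times))
  cf <- stats::lm.fit(X, values)$coefficients
  fitted_sinusoid(offset = cf[1],
                  amplitude = sqrt(cf[2]^2 + cf[3]^2),
                  omega = omega,
                  phase = atan2(cf[3], cf[2]))
}

#' @rdname fit_sinusoid
#' @param offset,amplitude,phase sinusoid parameters.
#' @export
fitted_sinusoid <- function(offset, amplitude, omega, phase) {
  stopifnot(amplitude >= 0, omega > 0)
  structure(list(offset = unname(offset), amplitude = unname(amplitude),
                 omega = omega, phase = unname(phase)),
            class = "fitted_sinusoid")
}

#' @export
print.fitted_sinusoid <- function(x, ...) {
  cat(sprintf(
    "<fitted_sinusoid> %.4g + %.4g sin(%.4g t %+.4g)\n",
    x$offset, x$amplitude, x$omega, x$phase))
  invisible(x)
}

#' Evaluate a fitted sinusoid
#' @param fit a `fitted_sinusoid`.
#' @param t times.
#' @export
sinusoid_at <- function(fit, t)
  fit$offset + fit$amplitude * sin(fit$omega * t + fit$phase)

#' Invert the observed mean oscillation to the upstream transcription rate
#'
#' If the ensemble mean of the copy number is sinusoidal, beta + A sin(omega
#' t + phi), and degradation is a constant lambda, the upstream
#' transcription rate is sinusoidal at the same frequency with offset
#' lambda beta, amplitude A sqrt(lambda^2 + omega^2), and phase advanced by
#' the transcriptional lag arctan(omega/lambda). The lag is bounded between
#' 0 (fast degradation) and pi/2 (slow degradation).
#'
#' @param fit `fitted_sinusoid` of the observed ensemble mean.
#' @param lam constant degradation rate.
#' @return `fitted_sinusoid` of the inferred transcription rate.
#' @export
infer_upstream_sinusoid <- function(fit, lam) {
  stopifnot(inherits(fit, "fitted_sinusoid"), lam > 0)
  fitted_sinusoid(offset = lam * fit$offset,
                  amplitude = fit$amplitude * sqrt(lam^2 + fit$omega^2),
                  omega = fit$omega,
                  phase = fit$phase + atan(fit$omega / lam))
}

#' Convert a phase lag to a time delay
#'
#' delay = lag / omega (one full period for lag = 2 pi).
#'
#' @param lag phase lag in radians.
#' @param omega angular frequency (> 0).
#' @return Time delay in the units of 1/omega.
#' @export
phase_to_delay <- function(lag, omega) {
  if (omega <= 0) stop("omega must be positive")
  lag / omega
}
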