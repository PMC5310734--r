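#' Truncated copy-number distributions
#'
#' A `copy_number_dist` stores the probability mass function P(n, t) of the
#' mRNA copy number on n = 0..n_max together with the time stamp and the
#' estimated mass beyond the truncation.
#'
#' @param pmf numeric vector of probabilities for n = 0..length(pmf)-1.
#' @param time time stamp (may be `NA` for stationary distributions).
#' @param truncation_tail estimated probability mass beyond n_max.
#' @return An object of class `copy_number_dist`.
#' @export
copy_number_dist <- function(pmf, time = NA_real_, truncation_tail = NULL) {
  pmf <- as.numeric(pmf)
  if (any(pmf < -1e-12) || any(pmf > 1 + 1e-12))
    stop("pmf entries must lie in [0, 1]")
  pmf <- pmin(pmax(pmf, 0), 1)
  if (is.null(truncation_tail)) truncation_tail <- max(0, 1 - sum(pmf))
  if (abs(sum(pmf) + truncation_tail - 1) > 1e-9)
    stop("pmf + truncation tail must sum to 1 within 1e-9")
  structure(list(n = seq_along(pmf) - 1L, pmf = pmf, time = time,
                 truncation_tail = truncation_tail),
            class = "copy_number_dist")
}

#' @export
print.copy_number_dist <- function(x, ...) {
  cat(sprintf("<copy_number_dist> n_max=%d, t=%s, tail=%.3g, mean=%.4g\n",
              max(x$n), format(x$time), x$truncation_tail, dist_mean(x)))
  invisible(x)
}

#' Moments of a truncated copy-number distribution
#' @param d a `copy_number_dist`.
#' @return mean / variance / Fano factor of the truncated pmf.
#' @export
dist_mean <- function(d) sum(d$n * d$pmf)

#' @rdname dist_mean
#' @export
dist_var <- function(d) sum(d$n^2 * d$pmf) - dist_mean(d)^2

#' Total variation distance between two copy-number distributions
#'
#' TV(p, q) = 0.5 * sum |p_n - q_n|, with the shorter pmf zero-padded.
#' @param a,b `copy_number_dist` objects (or bare pmf vectors).
#' @export
tv_distance <- function(a, b) {
  pa <- if (inherits(a, "copy_number_dist")) a$pmf else as.numeric(a)
  pb <- if (inherits(b, "copy_number_dist")) b$pmf else as.numeric(b)
  n <- max(length(pa), length(pb))
  pa <- c(pa, numeric(n - length(pa)))
  pb <- c(pb, numeric(n - length(pb)))
  0.5 * sum(abs(pa - pb))
}

#' Long-term synchronous distribution: Poisson with the effective drive
#'
#' Once the burn-in transient has decayed, the copy-number distribution of a
#' perfectly synchronous population is Poisson with parameter chi(t).
#'
#' @param chi_value value of the effective drive (non-negative).
#' @param n_max truncation; auto-extended until the recorded tail is below
#'   `tail_tol`.
#' @param tail_tol tail tolerance (default 1e-10).
#' @param time optional time stamp.
#' @return A `copy_number_dist`.
#' @export
longterm_pmf <- function(chi_value, n_max = NULL, tail_tol = 1e-10,
                         time = NA_real_) {
  if (!is.finite(chi_value) || chi_value < 0)
    stop("the Poisson parameter chi must be non-negative")
  if (is.null(n_max)) n_max <- default_nmax(chi_value)
  repeat {
    tail <- stats::ppois(n_max, chi_value, lower.tail = FALSE)
    if (tail < tail_tol || n_max > 1e7) break
    n_max <- 2L * n_max + 10L
  }
  copy_number_dist(stats::dpois(0:n_max, chi_value), time = time,
                   truncation_tail = tail)
}

default_nmax <- function(mean_level)
  as.integer(ceiling(max(10, mean_level + 10 * sqrt(mean_level + 1))))

#' Exact synchronous solution of the master equation
#'
#' For a perfectly synchronous population started with `n0` molecules, the
#' solution of the master equation at time t is the convolution of a
#' Binomial(n0, p(t)) of surviving initial transcripts, with survival
#' probability p(t) = exp(-int lambda), and a Poisson(chi(t)) of transcripts
#' produced since t0. A distribution-valued initial condition is handled by
#' mixing over n0.
#'
#' @param initial either a single non-negative integer `n0`, or a
#'   `copy_number_dist` giving the distribution of the initial copy number.
#' @param mu,lam transcription and degradation `rate_path`s.
#' @param t query time (at or after the origin `t0`).
#' @param t0 origin time of the initial condition (default 0).
#' @param n_max truncation, auto-extended until `tail_tol` met.
#' @param tail_tol tail tolerance (default 1e-10).
#' @return A `copy_number_dist` at time `t`.
#' @export
synchronous_pmf <- function(initial, mu, lam, t, t0 = 0, n_max = NULL,
                            tail_tol = 1e-10) {
  if (t < t0) stop("query time precedes the origin of the initial condition")
  if (t == t0) {
    if (inherits(initial, "copy_number_dist")) return(initial)
    pmf <- numeric(initial + 1L); pmf[initial + 1L] <- 1
    return(copy_number_dist(pmf, time = t, truncation_tail = 0))
  }
  n_internal <- max(64L, 16L * ceiling((t - t0)))
  chi <- solve_effective_drive(mu, lam, 0,
                               seq(t0, t, length.out = n_internal))
  chi_t <- chi_at(chi, t)
  p_surv <- exp(-rate_integral(lam, t0, t))

  if (inherits(initial, "copy_number_dist")) {
    w <- initial$pmf
    n0s <- initial$n
  } else {
    stopifnot(length(initial) == 1L, initial >= 0, initial == round(initial))
    w <- 1; n0s <- as.integer(initial)
  }
  if (is.null(n_max))
    n_max <- default_nmax(chi_t + max(n0s) * p_surv)
  repeat {
    pmf <- numeric(n_max + 1L)
    pois <- stats::dpois(0:n_max, chi_t)
    for (k in seq_along(n0s)) {
      if (w[k] == 0) next
      n0 <- n0s[k]
      if (n0 == 0L) { pmf <- pmf + w[k] * pois; next }
      surv <- stats::dbinom(0:min(n0, n_max), n0, p_surv)
      pmf <- pmf + w[k] * conv_trunc(surv, pois, n_max)
    }
    tail <- max(0, 1 - sum(pmf))
    if (tail < tail_tol || n_max > 1e6) break
    n_max <- 2L * n_max + 10L
  }
  copy_number_dist(pmf, time = t, truncation_tail = tail)
}

# truncated convolution of two pmfs up to n_max
conv_trunc <- function(a, b, n_max) {
  out <- numeric(n_max + 1L)
  for (i in seq_along(a)) {
    ia <- i - 1L
    jmax <- n_max - ia
    if (jmax < 0L) break
    idx <- seq_len(min(length(b), jmax + 1L))
    out[ia + idx] <- out[ia + idx] + a[i] * b[idx]
  }
  out
}
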