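#' Time-varying transcription or degradation rate paths
#'
#' A `rate_path` is one cell's drive: a non-negative rate as a function of
#' time, tagged as either a transcription or a degradation rate. Paths can be
#' given as an arbitrary vectorised function of time, or as a
#' piecewise-constant step function with explicit breakpoints
#' (right-continuous, the telegraph convention).
#'
#' @param fun vectorised function of time returning non-negative rates.
#' @param domain length-2 numeric, closed time interval on which the path is
#'   defined.
#' @param kind `"transcription"` or `"degradation"`.
#' @return An object of class `rate_path`.
#' @export
rate_path <- function(fun, domain = c(0, Inf), kind = "transcription") {
  stopifnot(is.function(fun), length(domain) == 2L, domain[1] < domain[2])
  kind <- match.arg(kind, c("transcription", "degradation"))
  structure(list(fun = fun, domain = as.numeric(domain), kind = kind,
                 piecewise = FALSE),
            class = "rate_path")
}

#' @rdname rate_path
#' @param value constant rate level.
#' @export
rate_path_constant <- function(value, domain = c(0, Inf),
                               kind = "transcription") {
  stopifnot(is.finite(value), value >= 0)
  p <- rate_path(function(t) rep.int(value, length(t)), domain, kind)
  p$constant <- value
  p
}

#' @rdname rate_path
#' @param offset,amplitude,omega,phase sinusoid `offset + amplitude *
#'   sin(omega * t + phase)`; must stay non-negative.
#' @export
rate_path_sinusoid <- function(offset, amplitude, omega, phase = 0,
                               domain = c(0, Inf), kind = "transcription") {
  stopifnot(offset >= 0, amplitude >= 0, omega > 0)
  if (amplitude > offset + 1e-12)
    stop("sinusoidal rate would go negative: amplitude > offset")
  rate_path(function(t) offset + amplitude * sin(omega * t + phase),
            domain, kind)
}

#' @rdname rate_path
#' @param times increasing breakpoint times, first element is the start of
#'   the domain.
#' @param values rate level on each interval `[times[i], times[i+1])`; one
#'   value per breakpoint (the last extends to `t_end`).
#' @param t_end end of the domain.
#' @export
rate_path_piecewise <- function(times, values, t_end = max(times),
                                kind = "transcription") {
  stopifnot(length(times) == length(values), !is.unsorted(times),
            all(values >= 0), all(is.finite(values)), t_end >= max(times))
  times <- as.numeric(times); values <- as.numeric(values)
  f <- function(t) values[pmax(1L, findInterval(t, times))]
  p <- rate_path(f, c(times[1], t_end), kind)
  p$piecewise <- TRUE
  p$breaks <- times
  p$levels <- values
  p
}

#' Evaluate a rate path
#'
#' @param path a `rate_path`.
#' @param t numeric vector of times within the path's domain.
#' @return Numeric vector of rates.
#' @export
rate_at <- function(path, t) {
  stopifnot(inherits(path, "rate_path"))
  if (any(t < path$domain[1] - 1e-12) || any(t > path$domain[2] + 1e-12))
    stop("time outside the rate path domain")
  r <- path$fun(t)
  if (any(!is.finite(r)) || any(r < 0))
    stop("rate path returned a negative or non-finite rate")
  r
}

#' @export
print.rate_path <- function(x, ...) {
  cat(sprintf("<rate_path> kind=%s domain=[%g, %g]%s\n", x$kind,
              x$domain[1], x$domain[2],
              if (isTRUE(x$piecewise))
                sprintf(" piecewise-constant (%d breakpoints)",
                        length(x$breaks)) else ""))
  invisible(x)
}

# sup of the rate over [t1, t2], estimated on a dense grid (used for
# thinning bounds and validation)
rate_sup <- function(path, t1, t2, n = 2048L) {
  if (isTRUE(path$piecewise)) {
    i1 <- max(1L, findInterval(t1, path$breaks))
    i2 <- max(1L, findInterval(t2, path$breaks))
    return(max(path$levels[i1:i2]))
  }
  if (!is.null(path$constant)) return(path$constant)
  v <- rate_at(path, seq(t1, t2, length.out = n))
  # grid max plus the largest between-sample increment: a safe upper bound
  # for paths of bounded variation (the excursion between two adjacent
  # samples cannot exceed the neighbouring increments' scale)
  max(v) + max(abs(diff(v)))
}

# integral of the rate over [t0, t1]; exact for piecewise-constant and
# constant paths, adaptive quadrature otherwise
rate_integral <- function(path, t0, t1) {
  if (t1 == t0) return(0)
  stopifnot(t1 > t0)
  if (!is.null(path$constant)) return(path$constant * (t1 - t0))
  if (isTRUE(path$piecewise)) {
    bp <- c(path$breaks, path$domain[2])
    knots <- sort(unique(c(t0, t1, bp[bp > t0 & bp < t1])))
    lev <- path$levels[pmax(1L, findInterval(knots[-length(knots)],
                                             path$breaks))]
    return(sum(lev * diff(knots)))
  }
  stats::integrate(function(s) rate_at(path, s), t0, t1,
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}
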