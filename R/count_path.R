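#' Single-cell copy-number trajectories
#'
#' A `count_path` is a piecewise-constant (right-continuous) record of the
#' mRNA copy number of one cell: `counts[i]` holds on
#' `[times[i], times[i+1])`, and the last value holds up to `t_end`.
#'
#' @param times increasing event or sample times.
#' @param counts non-negative integer counts, one per time.
#' @param t_end end of the observation span (default `max(times)`).
#' @param event_resolved `TRUE` if `times` are reaction events (counts then
#'   change by +-1 between consecutive entries); sampled paths relax this.
#' @param seed optional seed recorded for provenance.
#' @return An object of class `count_path`.
#' @export
count_path <- function(times, counts, t_end = max(times),
                       event_resolved = TRUE, seed = NULL) {
  stopifnot(length(times) == length(counts), !is.unsorted(times),
            all(counts >= 0), all(counts == round(counts)),
            t_end >= max(times))
  if (event_resolved && length(counts) > 1L &&
      any(abs(diff(counts)) != 1))
    stop("event-resolved paths must change counts by +-1 at event times")
  structure(list(times = as.numeric(times), counts = as.integer(counts),
                 t_end = t_end, event_resolved = event_resolved,
                 seed = seed),
            class = "count_path")
}

#' Evaluate a count path
#' @param path a `count_path`.
#' @param t times within the span.
#' @return Integer counts at the query times.
#' @export
count_at <- function(path, t) {
  stopifnot(inherits(path, "count_path"))
  if (any(t < path$times[1] - 1e-9) || any(t > path$t_end + 1e-9))
    stop("time outside the count path span")
  path$counts[pmax(1L, findInterval(t, path$times))]
}

#' @export
print.count_path <- function(x, ...) {
  cat(sprintf("<count_path> %d records on [%g, %g]%s\n", length(x$times),
              x$times[1], x$t_end,
              if (x$event_resolved) " (event-resolved)" else " (sampled)"))
  invisible(x)
}
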