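#' Text serialisation of core objects
#'
#' All on-disk artefacts are plain text: tab-separated tables with a
#' self-describing comment header (`#` lines recording the object kind,
#' tool version, time stamps and any provenance fields), plus JSON for
#' configuration. Round-trips preserve the numeric content to full double
#' precision.
#'
#' @name txdrive-io
NULL

io_header <- function(kind, fields = list()) {
  fields <- c(list(object = kind,
                   tool = paste0("txdrive ",
                                 as.character(utils::packageVersion("txdrive")))),
              fields)
  vapply(names(fields), function(nm)
    sprintf("# %s: %s", nm, format(fields[[nm]], digits = 17)),
    character(1))
}

io_write_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

io_read_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^# ([^:]+): (.*)$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.table(text = lines[-hdr], header = TRUE, sep = "\t")
  list(meta = meta, data = df)
}

#' Write / read a rate path as a sampled table
#'
#' The path is written as a two-column `time`/`rate` table (for piecewise
#' paths, at its breakpoints just before and after each jump; otherwise on
#' `n` uniform samples over `domain`); reading reconstructs a
#' piecewise-constant or piecewise-linear `rate_path`.
#'
#' @param path a `rate_path`.
#' @param file output file.
#' @param domain sampling window (default the path domain; must be finite).
#' @param n number of samples for non-piecewise paths (default 512).
#' @return The file path, invisibly.
#' @export
write_rate_path <- function(path, file, domain = NULL, n = 512L) {
  stopifnot(inherits(path, "rate_path"))
  if (is.null(domain)) domain <- path$domain
  if (!all(is.finite(domain)))
    stop("need a finite sampling window for an unbounded rate path domain")
  if (isTRUE(path$piecewise)) {
    brk <- path$breaks[path$breaks >= domain[1] & path$breaks <= domain[2]]
    brk <- sort(unique(c(domain[1], brk)))
    eps <- max(1e-9, 1e-9 * diff(domain))
    pre <- brk[brk > domain[1]] - eps          # pre-jump samples
    tt <- sort(unique(c(brk, pre[pre >= domain[1]], domain[2])))
    repr <- "piecewise_constant"
  } else {
    tt <- seq(domain[1], domain[2], length.out = n)
    repr <- "sampled_linear"
  }
  df <- data.frame(time = tt, rate = rate_at(path, tt))
  io_write_table(df, file,
                 io_header("rate_path",
                           list(kind = path$kind, representation = repr)))
}

#' @rdname write_rate_path
#' @export
read_rate_path <- function(file) {
  r <- io_read_table(file)
  if (!identical(r$meta$object, "rate_path"))
    stop("file does not contain a rate_path")
  kind <- if (is.null(r$meta$kind)) "transcription" else r$meta$kind
  tt <- r$data$time; vv <- r$data$rate
  if (identical(r$meta$representation, "piecewise_constant")) {
    t_end <- tt[length(tt)]
    tol <- 1e-8 * max(1, abs(t_end))
    # keep the last (post-jump) sample of each near-duplicate time group
    keep <- c(diff(tt) > tol, TRUE)
    bt <- tt[keep]; bv <- vv[keep]
    if (length(bt) > 1L && abs(bt[length(bt)] - t_end) < tol &&
        bv[length(bt)] == bv[length(bt) - 1L]) {
      bt <- bt[-length(bt)]; bv <- bv[-length(bv)]
    }
    # drop pre-jump samples: each break carries its right-continuous level
    chg <- c(TRUE, bv[-1] != bv[-length(bv)])
    rate_path_piecewise(bt[chg], bv[chg], t_end = t_end, kind = kind)
  } else {
    f <- stats::approxfun(tt, vv, rule = 2)
    rate_path(f, c(tt[1], tt[length(tt)]), kind)
  }
}

#' Write / read a copy-number distribution
#'
#' Two-column `n`/`probability` table; the header records the time stamp
#' and the truncation tail mass.
#'
#' @param dist a `copy_number_dist`.
#' @param file output file.
#' @return The file path, invisibly.
#' @export
write_copy_number_dist <- function(dist, file) {
  stopifnot(inherits(dist, "copy_number_dist"))
  df <- data.frame(n = seq_along(dist$pmf) - 1L, probability = dist$pmf)
  io_write_table(df, file,
                 io_header("copy_number_dist",
                           list(time = dist$time,
                                truncation_tail = dist$truncation_tail)))
}

#' @rdname write_copy_number_dist
#' @export
read_copy_number_dist <- function(file) {
  r <- io_read_table(file)
  if (!identical(r$meta$object, "copy_number_dist"))
    stop("file does not contain a copy_number_dist")
  tm <- suppressWarnings(as.numeric(r$meta$time))
  tail <- suppressWarnings(as.numeric(r$meta$truncation_tail))
  if (!is.finite(tail)) tail <- 0
  copy_number_dist(r$data$probability, time = tm, truncation_tail = tail)
}

#' Write / read a count path
#'
#' Two-column `time`/`count` table of the event (or sample) record.
#'
#' @param path a `count_path`.
#' @param file output file.
#' @return The file path, invisibly.
#' @export
write_count_path <- function(path, file) {
  stopifnot(inherits(path, "count_path"))
  df <- data.frame(time = path$times, count = path$counts)
  io_write_table(df, file,
                 io_header("count_path",
                           list(t_end = path$t_end,
                                event_resolved = path$event_resolved,
                                seed = if (is.null(path$seed)) NA
                                       else path$seed)))
}

#' @rdname write_count_path
#' @export
read_count_path <- function(file) {
  r <- io_read_table(file)
  if (!identical(r$meta$object, "count_path"))
    stop("file does not contain a count_path")
  seed <- suppressWarnings(as.integer(r$meta$seed))
  count_path(r$data$time, r$data$count,
             t_end = as.numeric(r$meta$t_end),
             event_resolved = isTRUE(as.logical(r$meta$event_resolved)),
             seed = if (is.na(seed)) NULL else seed)
}

#' Write / read a state density field
#'
#' Columns `x`, `f_state1` .. `f_stateD` of cell-average densities; the
#' header records the time stamp.
#'
#' @param field a `state_density_field`.
#' @param file output file.
#' @return The file path, invisibly.
#' @export
write_state_density_field <- function(field, file) {
  stopifnot(inherits(field, "state_density_field"))
  df <- data.frame(x = field$x, field$per_state)
  names(df) <- c("x", paste0("f_state", seq_len(ncol(field$per_state))))
  io_write_table(df, file,
                 io_header("state_density_field",
                           list(time = field$time,
                                n_states = ncol(field$per_state))))
}

#' @rdname write_state_density_field
#' @export
read_state_density_field <- function(file) {
  r <- io_read_table(file)
  if (!identical(r$meta$object, "state_density_field"))
    stop("file does not contain a state_density_field")
  state_density_field(r$data$x, as.matrix(r$data[-1L]),
                      time = suppressWarnings(as.numeric(r$meta$time)))
}

#' Read a JSON configuration file
#'
#' Thin wrapper over jsonlite with scalar simplification, used by the
#' command-line interface.
#'
#' @param file JSON file path.
#' @return A named list.
#' @export
read_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  jsonlite::read_json(file, simplifyVector = TRUE)
}
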