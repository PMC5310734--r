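#' Multistate Fokker-Planck-Kolmogorov solver
#'
#' Conservative finite-volume discretisation of the coupled
#' advection + Markov-switching system
#' \deqn{\partial_t f_s = -\partial_x[(m_s - \lambda_s x) f_s] +
#'   \sum_r K_{sr} f_r,}
#' the evolution equation of the joint density of the effective drive and
#' the promoter state. The drift velocity m_s - lambda_s x points inward at
#' both ends of [0, x_max], so no-flux boundaries emerge naturally and the
#' scheme conserves total probability exactly.
#'
#' @name fpk
NULL

#' State density field
#'
#' Cell-average densities f_s(x, t) of each promoter state on a uniform
#' finite-volume grid.
#'
#' @param x_mid cell midpoints (uniform spacing).
#' @param per_state matrix (cells x D) of non-negative cell-average
#'   densities; total mass must be 1 within 1e-6.
#' @param time time stamp.
#' @return An object of class `state_density_field`.
#' @export
state_density_field <- function(x_mid, per_state, time = NA_real_) {
  per_state <- as.matrix(per_state)
  stopifnot(nrow(per_state) == length(x_mid))
  if (any(per_state < -1e-9)) stop("state densities must be non-negative")
  per_state <- pmax(per_state, 0)
  dx <- x_mid[2] - x_mid[1]
  mass <- sum(per_state) * dx
  if (abs(mass - 1) > 1e-6)
    stop(sprintf("state density field mass %.8f differs from 1", mass))
  structure(list(x = x_mid, per_state = per_state, dx = dx, time = time),
            class = "state_density_field")
}

#' @export
print.state_density_field <- function(x, ...) {
  cat(sprintf("<state_density_field> %d cells x %d states, t=%s\n",
              length(x$x), ncol(x$per_state), format(x$time)))
  invisible(x)
}

# sparse semi-discrete operator (advection upwind + switching), acting on
# the stacked vector of cell averages, state-major within cells
fpk_operator <- function(model, n_cells, x_max) {
  D <- model$D
  dx <- x_max / n_cells
  faces <- seq(0, x_max, length.out = n_cells + 1L)
  idx <- function(cell, s) (cell - 1L) * D + s
  ii <- list(); jj <- list(); vv <- list()
  p <- 0L
  add <- function(i, j, v) {
    p <<- p + 1L
    ii[[p]] <<- i; jj[[p]] <<- j; vv[[p]] <<- v
  }
  # interior faces k = 2..n_cells (face k sits between cells k-1 and k);
  # boundary faces carry no flux (velocity points inward there)
  for (s in seq_len(D)) {
    k <- 2:n_cells
    v <- model$m_s[s] - model$lam_s[s] * faces[k]
    up <- ifelse(v >= 0, k - 1L, k)
    add(idx(k - 1L, s), idx(up, s), -v / dx)
    add(idx(k, s), idx(up, s), v / dx)
  }
  cells <- seq_len(n_cells)
  for (s in seq_len(D)) for (r in seq_len(D)) {
    if (model$K[s, r] == 0 && s != r) next
    add(idx(cells, s), idx(cells, r), rep(model$K[s, r], n_cells))
  }
  ii <- unlist(ii); jj <- unlist(jj); vv <- unlist(vv)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(n_cells * D, n_cells * D))
  list(A = A, dx = dx, x_mid = (faces[-1L] + faces[-(n_cells + 1L)]) / 2,
       v_max = max(abs(outer(model$m_s, faces,
                             function(m, x) m) -
                       outer(model$lam_s, faces, `*`))))
}

default_xmax <- function(model) 1.05 * max(model$m_s / model$lam_s)

field_to_vec <- function(field) as.vector(t(field$per_state))
vec_to_mat <- function(v, D) matrix(v, ncol = D, byrow = TRUE)

#' Evolve the FPK system
#'
#' Method-of-lines: first-order upwind fluxes in x, explicit RK4 in time
#' with a CFL-limited step (the semi-discrete system is linear and the
#' scheme conserves mass to rounding).
#'
#' @param model a `promoter_model`.
#' @param initial a `state_density_field` (its grid fixes the
#'   discretisation; `x_max` must cover all fixed points m_s/lambda_s).
#' @param t_grid increasing output times, starting at the initial time.
#' @param cfl Courant number (default 0.45).
#' @return List of `state_density_field`s, one per output time.
#' @export
fpk_solve <- function(model, initial, t_grid, cfl = 0.45) {
  stopifnot(inherits(model, "promoter_model"),
            inherits(initial, "state_density_field"),
            !is.unsorted(t_grid, strictly = TRUE))
  n_cells <- length(initial$x)
  x_max <- initial$x[n_cells] + initial$dx / 2
  if (x_max < max(model$m_s / model$lam_s) - 1e-9)
    stop("grid upper end below the largest drive fixed point m_s/lambda_s")
  op <- fpk_operator(model, n_cells, x_max)
  A <- op$A
  k_max <- max(abs(diag(model$K)))
  dt_cfl <- cfl * op$dx / max(op$v_max, 1e-12)
  dt_switch <- if (k_max > 0) 1 / k_max else Inf
  dt <- min(dt_cfl, dt_switch)
  f <- field_to_vec(initial)
  out <- vector("list", length(t_grid))
  out[[1L]] <- initial
  t_now <- t_grid[1]
  for (k in 2L:length(t_grid)) {
    span <- t_grid[k] - t_now
    nsub <- max(1L, ceiling(span / dt))
    h <- span / nsub
    for (s in seq_len(nsub)) {
      k1 <- A %*% f
      k2 <- A %*% (f + h / 2 * k1)
      k3 <- A %*% (f + h / 2 * k2)
      k4 <- A %*% (f + h * k3)
      f <- as.numeric(f + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    }
    t_now <- t_grid[k]
    mass <- sum(f) * op$dx
    if (abs(mass - 1) > 1e-6 * max(1, abs(t_grid[k] - t_grid[1])))
      stop("FPK mass conservation failure")
    out[[k]] <- state_density_field(op$x_mid,
                                    vec_to_mat(pmax(f, 0) / mass, model$D),
                                    time = t_grid[k])
  }
  out
}

#' Stationary state of the FPK system
#'
#' Null vector of the sparse discrete operator (direct solve with a
#' normalisation row replacing one balance equation), for an irreducible
#' promoter chain.
#'
#' @param model a `promoter_model`.
#' @param n_cells finite-volume cells (default 8192; the upwind scheme is
#'   first-order, so the density error scales like 1/n_cells).
#' @param x_max grid upper end (default 1.05 max m_s/lambda_s).
#' @return A `state_density_field` (time `NA`).
#' @export
fpk_steady_state <- function(model, n_cells = 8192L, x_max = NULL) {
  stopifnot(inherits(model, "promoter_model"))
  check_irreducible(model$K)
  if (is.null(x_max)) x_max <- default_xmax(model)
  op <- fpk_operator(model, n_cells, x_max)
  N <- n_cells * model$D
  A <- op$A
  A[N, ] <- op$dx                      # normalisation row: total mass = 1
  rhs <- c(numeric(N - 1L), 1)
  f <- as.numeric(Matrix::solve(A, rhs))
  neg <- min(f)
  if (neg < -1e-6) warning("steady-state solve produced negative densities")
  f <- pmax(f, 0)
  f <- f / (sum(f) * op$dx)
  state_density_field(op$x_mid, vec_to_mat(f, model$D), time = NA_real_)
}

#' Marginalise a state density field over the promoter state
#'
#' f_X(x, t) = sum_s f_s(x, t) on the same grid.
#'
#' @param field a `state_density_field`.
#' @return A `drive_density` (cell-average representation).
#' @export
marginalize_density <- function(field) {
  stopifnot(inherits(field, "state_density_field"))
  f <- rowSums(field$per_state)
  drive_density(x = field$x, f = f, support = c(field$x[1] - field$dx / 2,
                                                field$x[length(field$x)] +
                                                  field$dx / 2),
                time = field$time, w = rep(field$dx, length(field$x)),
                normalize_tol = 1e-6)
}

#' Per-state probability masses of a field
#' @param field a `state_density_field`.
#' @return Numeric vector of state masses (sums to 1).
#' @export
field_state_masses <- function(field) colSums(field$per_state) * field$dx
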