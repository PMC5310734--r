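#' Truncated chemical master equation oracle
#'
#' Direct linear-algebra solution of the master equation on the truncated
#' state space (n, s), n <= n_max: transient solutions via the action of
#' the matrix exponential of the generator, stationary solutions via its
#' null vector. Serves as an independent oracle for the Poisson-mixture
#' assembly and the simulators.
#'
#' @param model a `promoter_model`, or a list `list(m =, lam =)` of
#'   constant synchronous rates.
#' @param n_max copy-number truncation; auto-enlarged until the stationary
#'   boundary mass is below `flux_tol`.
#' @param t query time for the transient solution, or `NULL` for the
#'   stationary solution.
#' @param initial optional initial distribution over the (n, s) space:
#'   list with `pmf` (over n) and `state_probs` (over s); default all mass
#'   at n = 0 with stationary promoter occupancy.
#' @param flux_tol boundary-mass tolerance (default 1e-10).
#' @return A `copy_number_dist` (marginal over promoter states); per-state
#'   joint solution in attribute `joint` (matrix (n_max+1) x D).
#' @export
cme_truncated_solve <- function(model, n_max = NULL, t = NULL,
                                initial = NULL, flux_tol = 1e-10) {
  if (!inherits(model, "promoter_model")) {
    stopifnot(is.list(model), model$m >= 0, model$lam > 0)
    model <- promoter_model(model$m, model$lam, matrix(0, 1, 1))
  }
  D <- model$D
  if (is.null(n_max))
    n_max <- default_nmax(max(model$m_s / model$lam_s))
  repeat {
    G <- cme_generator(model, n_max)
    if (is.null(t)) {
      N <- (n_max + 1L) * D
      A <- G
      A[N, ] <- 1
      p <- as.numeric(Matrix::solve(A, c(numeric(N - 1L), 1)))
    } else {
      p0 <- cme_initial_vec(model, n_max, initial)
      E <- Matrix::expm(G * t)
      p <- as.numeric(E %*% p0)
    }
    p <- pmax(p, 0); p <- p / sum(p)
    joint <- matrix(p, ncol = D, byrow = TRUE)   # row n, col s
    boundary <- sum(joint[n_max + 1L, ])
    if (boundary < flux_tol || n_max > 5000L) break
    n_max <- ceiling(n_max * 1.5) + 10L
  }
  if (boundary >= flux_tol)
    stop("CME truncation could not be enlarged enough: boundary mass ",
         format(boundary))
  pmf <- rowSums(joint)
  out <- copy_number_dist(pmf / sum(pmf),
                          time = if (is.null(t)) NA_real_ else t,
                          truncation_tail = 0)
  attr(out, "joint") <- joint
  out
}

# sparse generator on states (n, s), state-major within n-blocks, columns
# are source states (dP/dt = G P)
cme_generator <- function(model, n_max) {
  D <- model$D
  nn <- 0:n_max
  idx <- function(n, s) n * D + s          # n from 0
  ii <- list(); jj <- list(); vv <- list(); p <- 0L
  add <- function(i, j, v) {
    p <<- p + 1L
    ii[[p]] <<- i; jj[[p]] <<- j; vv[[p]] <<- v
  }
  for (s in seq_len(D)) {
    m <- model$m_s[s]; l <- model$lam_s[s]
    # transcription n -> n+1 (absorbed at the truncation boundary)
    n_from <- 0:(n_max - 1L)
    add(idx(n_from + 1L, s), idx(n_from, s), rep(m, n_max))
    add(idx(n_from, s), idx(n_from, s), rep(-m, n_max))
    # degradation n -> n-1
    n_from <- 1:n_max
    add(idx(n_from - 1L, s), idx(n_from, s), l * n_from)
    add(idx(n_from, s), idx(n_from, s), -l * n_from)
  }
  if (D > 1L) for (s in seq_len(D)) for (r in seq_len(D)) {
    if (model$K[s, r] == 0) next
    add(idx(nn, s), idx(nn, r), rep(model$K[s, r], n_max + 1L))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c((n_max + 1L) * D, (n_max + 1L) * D))
}

cme_initial_vec <- function(model, n_max, initial) {
  D <- model$D
  state_probs <- if (!is.null(initial$state_probs)) initial$state_probs
    else if (D == 1L) 1 else stationary_occupancy(model)
  pmf <- if (!is.null(initial$pmf)) initial$pmf else c(1, numeric(n_max))
  pmf <- c(pmf, numeric(max(0L, n_max + 1L - length(pmf))))[1:(n_max + 1L)]
  as.vector(t(outer(pmf, state_probs)))
}

#' Burn-in transient of the random telegraph model
#'
#' Transient solution of the RT master equation from all probability at
#' n = 0 in the inactive promoter state; the total-variation distance to
#' the stationary Poisson-Beta mixture decays (essentially exponentially,
#' at the degradation rate) as the system forgets the initial condition.
#'
#' @param model an RT `promoter_model`.
#' @param t_grid increasing times (starting at 0).
#' @param n_max truncation (default from the drive maximum).
#' @return List with `dists` (list of `copy_number_dist`), `tv` (distance
#'   to stationarity at each time), `stationary` (the Poisson-Beta pmf).
#' @export
burn_in_demo <- function(model, t_grid, n_max = NULL) {
  p <- as_rt_params(model)
  if (is.null(n_max)) n_max <- default_nmax(p$m / p$lam)
  G <- cme_generator(model, n_max)
  p0 <- cme_initial_vec(model, n_max,
                        list(pmf = c(1, numeric(n_max)),
                             state_probs = c(1, 0)))   # inactive state
  stat_pmf <- poisson_beta_pmf(0:n_max, p$k_on / p$lam, p$k_off / p$lam,
                               p$m / p$lam)
  stationary <- copy_number_dist(stat_pmf / sum(stat_pmf),
                                 truncation_tail = 0)
  dists <- vector("list", length(t_grid))
  tv <- numeric(length(t_grid))
  vec <- p0
  t_prev <- 0
  E_step <- NULL; h_prev <- NA_real_
  for (k in seq_along(t_grid)) {
    h <- t_grid[k] - t_prev
    if (h > 0) {
      if (is.na(h_prev) || abs(h - h_prev) > 1e-12) {
        E_step <- Matrix::expm(G * h)
        h_prev <- h
      }
      vec <- as.numeric(E_step %*% vec)
    }
    t_prev <- t_grid[k]
    joint <- matrix(pmax(vec, 0), ncol = model$D, byrow = TRUE)
    pmf <- rowSums(joint); pmf <- pmf / sum(pmf)
    dists[[k]] <- copy_number_dist(pmf, time = t_grid[k],
                                   truncation_tail = 0)
    tv[k] <- tv_distance(dists[[k]], stationary)
  }
  list(times = t_grid, dists = dists, tv = tv, stationary = stationary)
}
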