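#' Exact stochastic simulation with time-varying rates
#'
#' Thinning (Lewis) algorithm for the immigration-death process with
#' time-dependent transcription rate mu(t) and degradation rate lambda(t):
#' candidate events are proposed from a piecewise-constant upper bound of
#' the total propensity, refreshed on a time mesh, and accepted with
#' probability (mu(t) + lambda(t) n) / bound. Exact in law: for constant
#' rates the snapshot distributions match the closed forms.
#'
#' @param mu transcription `rate_path`.
#' @param lam degradation `rate_path`.
#' @param n0 initial copy number.
#' @param t_end simulation end time.
#' @param seed RNG seed (recorded on the returned path).
#' @param rate_upper_bound optional global upper bound for mu; must
#'   dominate sup mu on [0, t_end] (validated on a dense grid). By default
#'   per-window bounds are computed from the path itself.
#' @param mesh_dt bound-refresh mesh width (default t_end/64).
#' @param t0 start time (default 0).
#' @return A `count_path` of the full event history.
#' @export
ssa_timevarying <- function(mu, lam, n0, t_end, seed = 1L,
                            rate_upper_bound = NULL, mesh_dt = NULL,
                            t0 = 0) {
  stopifnot(inherits(mu, "rate_path"), inherits(lam, "rate_path"),
            n0 >= 0, n0 == round(n0), t_end > t0)
  set.seed(seed)
  if (is.null(mesh_dt)) mesh_dt <- (t_end - t0) / 64
  mesh <- seq(t0, t_end, by = mesh_dt)
  if (mesh[length(mesh)] < t_end) mesh <- c(mesh, t_end)
  nw <- length(mesh) - 1L
  safety <- 1 + 1e-9
  mu_bound <- vapply(seq_len(nw), function(k)
    rate_sup(mu, mesh[k], mesh[k + 1L]) * safety, numeric(1))
  lam_bound <- vapply(seq_len(nw), function(k)
    rate_sup(lam, mesh[k], mesh[k + 1L]) * safety, numeric(1))
  if (!is.null(rate_upper_bound)) {
    if (any(mu_bound > rate_upper_bound * safety))
      stop("rate_upper_bound below the supremum of mu on [t0, t_end]")
    mu_bound[] <- rate_upper_bound
  }

  n <- as.integer(n0)
  t <- t0
  cap <- 256L
  ev_t <- numeric(cap); ev_n <- integer(cap)
  ev_t[1L] <- t0; ev_n[1L] <- n
  m <- 1L
  w <- 1L
  repeat {
    if (w > nw) break
    B <- mu_bound[w] + lam_bound[w] * n
    if (B <= 0) { t <- mesh[w + 1L]; w <- w + 1L; next }
    t_cand <- t + stats::rexp(1L, B)
    if (t_cand > mesh[w + 1L]) { t <- mesh[w + 1L]; w <- w + 1L; next }
    t <- t_cand
    a_mu <- rate_at(mu, t)
    a_death <- rate_at(lam, t) * n
    if (a_mu > mu_bound[w] || a_death > lam_bound[w] * n)
      stop("thinning upper bound violated at runtime")
    u <- stats::runif(1L) * B
    if (u < a_mu) {
      n <- n + 1L
    } else if (u < a_mu + a_death) {
      n <- n - 1L
    } else next                       # thinned (no event)
    m <- m + 1L
    if (m > cap) {
      cap <- 2L * cap
      ev_t <- c(ev_t, numeric(cap - length(ev_t)))
      ev_n <- c(ev_n, integer(cap - length(ev_n)))
    }
    ev_t[m] <- t; ev_n[m] <- n
  }
  count_path(ev_t[seq_len(m)], ev_n[seq_len(m)], t_end = t_end,
             event_resolved = TRUE, seed = seed)
}

#' Random telegraph activity path
#'
#' Alternating exponential holding times between the inactive (0) and
#' active (1) promoter states, with the initial state drawn from the
#' stationary occupancy k_on/(k_on + k_off).
#'
#' @param k_on,k_off switching rates (> 0).
#' @param t_end path length.
#' @param seed RNG seed.
#' @param levels rate levels mapped to the (inactive, active) states
#'   (default 0/1 activity).
#' @return A piecewise-constant `rate_path` (with attribute `states`).
#' @export
telegraph_path <- function(k_on, k_off, t_end, seed = 1L,
                           levels = c(0, 1)) {
  stopifnot(k_on > 0, k_off > 0, t_end > 0)
  set.seed(seed)
  p_on <- k_on / (k_on + k_off)
  state0 <- as.integer(stats::runif(1L) < p_on)   # 1 = active
  times <- 0; states <- state0
  t <- 0
  first <- state0
  # draw alternating exponential holding times in vectorised blocks
  while (t < t_end) {
    block <- max(64L, ceiling((t_end - t) * (k_on + k_off)))
    st_seq <- rep_len(c(first, 1L - first), block)
    hold <- stats::rexp(block, ifelse(st_seq == 1L, k_off, k_on))
    sw <- t + cumsum(hold)
    keep <- sw < t_end
    times <- c(times, sw[keep])
    states <- c(states, (1L - st_seq)[keep])
    t <- sw[block]
    first <- 1L - st_seq[block]
  }
  p <- rate_path_piecewise(times, levels[states + 1L], t_end = t_end,
                           kind = "transcription")
  p$states <- states
  p$seed <- seed
  p
}

#' Sample the effective drive across a population at a fixed time
#'
#' Draws `n_paths` independent realisations of the upstream drive model,
#' solves the effective-drive ODE along each, and returns chi(t): the fast
#' route to P(n, t), feeding [density_from_paths()] and [poisson_mixture()]
#' instead of event-level simulation.
#'
#' @param spec a model specification: a `promoter_model` (RT form), a
#'   `sinusoidal_entrainment`, or a `kuramoto_population`.
#' @param t snapshot time (for stationary sampling choose t >> 1/lambda).
#' @param n_paths number of independent drive paths.
#' @param seed RNG seed.
#' @param chi0 initial drive value at time 0 (default the model's mean
#'   drive, shortening the burn-in; use 0 to match trajectories started
#'   with zero molecules).
#' @return Numeric vector of chi values at time t.
#' @export
sample_chi_snapshot <- function(spec, t, n_paths, seed = 1L, chi0 = NULL) {
  stopifnot(t > 0, n_paths >= 1)
  if (inherits(spec, "promoter_model")) {
    p <- as_rt_params(spec)
    if (is.null(chi0))
      chi0 <- p$m / p$lam * p$k_on / (p$k_on + p$k_off)
    lam_path <- rate_path_constant(p$lam, c(0, t), "degradation")
    return(vapply(seq_len(n_paths), function(i) {
      tp <- telegraph_path(p$k_on, p$k_off, t, seed = seed + i,
                           levels = c(0, p$m))
      chi <- solve_effective_drive(tp, lam_path, chi0, c(0, t))
      chi_at(chi, t)
    }, numeric(1)))
  }
  if (inherits(spec, "sinusoidal_entrainment")) {
    set.seed(seed)
    phis <- stats::runif(n_paths, -spec$r, spec$r)
    if (spec$target == "transcription") {
      pp <- re_chi_params(spec)
      return(pp$A + pp$B * sin(spec$omega * t + phis - pp$psi))
    }
    stop("sampling for the degradation-target RE model is not implemented; ",
         "use re_degradation_density")
  }
  if (inherits(spec, "kuramoto_population")) {
    pop <- spec
    pop$C <- as.integer(n_paths)
    pop$seed <- as.integer(seed)
    dt <- 0.01 / max(abs(pop$omega_mean) + 4 * pop$omega_sd, pop$lam, 1)
    tg <- seq(0, t, length.out = max(64L, ceiling(t / dt)))
    cp <- kuramoto_chi_paths(pop, tg,
                             chi0 = if (is.null(chi0)) 0 else chi0)
    return(cp$chi[nrow(cp$chi), ])
  }
  stop("unknown model specification for drive sampling")
}

#' Reference upstream drive fixtures
#'
#' Three drive families with matched (expected) period T and matched
#' time-average level: a sinusoid, a square wave, and a random telegraph
#' process (expected waiting time T/2 in each state) -- the standard
#' periodic-versus-stochastic comparison set.
#'
#' @param kind `"sinusoid"`, `"square_wave"` or `"telegraph"`.
#' @param T_period period (or expected switching period) T.
#' @param mean_level time-average (or expectation) of the drive.
#' @param seed RNG seed (telegraph only).
#' @param t_end domain end (needed for the telegraph path; default 400 T).
#' @return A transcription `rate_path`.
#' @export
fixture_drives <- function(kind = c("sinusoid", "square_wave", "telegraph"),
                           T_period, mean_level, seed = 1L,
                           t_end = 400 * T_period) {
  kind <- match.arg(kind)
  stopifnot(T_period > 0, mean_level > 0)
  omega <- 2 * pi / T_period
  switch(kind,
    sinusoid = rate_path_sinusoid(mean_level, mean_level, omega,
                                  domain = c(0, Inf)),
    square_wave = {
      half <- T_period / 2
      n_half <- ceiling(t_end / half)
      rate_path_piecewise(times = (0:(n_half - 1L)) * half,
                          values = rep_len(c(2 * mean_level, 0), n_half),
                          t_end = n_half * half, kind = "transcription")
    },
    telegraph = telegraph_path(2 / T_period, 2 / T_period, t_end,
                               seed = seed, levels = c(0, 2 * mean_level))
  )
}
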