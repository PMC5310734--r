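#' D-state Markov promoter models
#'
#' A promoter switching stochastically between D discrete states s, each with
#' constant transcription rate m_s and degradation rate lambda_s, governed by
#' a continuous-time Markov chain with transition-rate matrix K, where
#' `K[s, r]` is the rate r -> s and diagonal entries are minus the column
#' exit rates (columns sum to zero).
#'
#' @param m_s per-state transcription rates (length D, non-negative).
#' @param lam_s per-state degradation rates (length D, positive).
#' @param K D x D transition-rate matrix (column-generator convention).
#' @return An object of class `promoter_model`.
#' @export
promoter_model <- function(m_s, lam_s, K) {
  K <- as.matrix(K)
  D <- length(m_s)
  stopifnot(length(lam_s) == D, nrow(K) == D, ncol(K) == D)
  if (any(m_s < 0)) stop("per-state transcription rates must be >= 0")
  if (any(lam_s <= 0)) stop("per-state degradation rates must be > 0")
  offdiag <- K; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal transition rates must be >= 0")
  if (any(abs(colSums(K)) > 1e-12))
    stop("columns of the transition-rate matrix must sum to zero")
  structure(list(D = D, m_s = as.numeric(m_s), lam_s = as.numeric(lam_s),
                 K = K),
            class = "promoter_model")
}

#' @rdname promoter_model
#' @param k_on,k_off activation / inactivation rates of the 2-state random
#'   telegraph (RT) promoter; state 1 = inactive (m=0), state 2 = active.
#' @param m transcription rate in the active state.
#' @param lam common degradation rate.
#' @export
rt_promoter <- function(k_on, k_off, m, lam) {
  stopifnot(k_on > 0, k_off > 0, m > 0, lam > 0)
  K <- matrix(c(-k_on, k_on, k_off, -k_off), 2, 2)
  p <- promoter_model(c(0, m), c(lam, lam), K)
  p$kind <- "rt"
  p$k_on <- k_on; p$k_off <- k_off; p$m <- m; p$lam <- lam
  p
}

#' @rdname promoter_model
#' @param k_star,k_1,k_2 cyclic transition rates of the 3-state refractory
#'   promoter: active s* -> inactive s1 -> refractory s2 -> s*; transcription
#'   at rate `m` only in s*. State order: (s*, s1, s2).
#' @export
refractory_promoter <- function(k_star, k_1, k_2, m, lam) {
  stopifnot(k_star > 0, k_1 > 0, k_2 > 0, m > 0, lam > 0)
  K <- matrix(0, 3, 3)
  K[2, 1] <- k_star; K[1, 1] <- -k_star
  K[3, 2] <- k_1;    K[2, 2] <- -k_1
  K[1, 3] <- k_2;    K[3, 3] <- -k_2
  p <- promoter_model(c(m, 0, 0), c(lam, lam, lam), K)
  p$kind <- "refractory"
  p$k_star <- k_star; p$k_1 <- k_1; p$k_2 <- k_2; p$m <- m; p$lam <- lam
  p
}

#' Stationary occupancy of the promoter chain
#'
#' Normalised null vector of the transition-rate matrix.
#' @param model a `promoter_model`.
#' @return Numeric vector of stationary state probabilities.
#' @export
stationary_occupancy <- function(model) {
  check_irreducible(model$K)
  D <- model$D
  A <- rbind(model$K[-D, , drop = FALSE], rep(1, D))
  pi <- solve(A, c(numeric(D - 1L), 1))
  if (any(pi < -1e-12)) stop("stationary occupancy solve failed")
  pmax(pi, 0) / sum(pmax(pi, 0))
}

check_irreducible <- function(K) {
  D <- nrow(K)
  adj <- (K > 0); diag(adj) <- TRUE
  reach <- adj
  for (i in seq_len(D)) reach <- (reach %*% adj) > 0 | reach
  if (!all(reach)) {
    bad <- which(!apply(reach, 2L, all))
    stop(sprintf("promoter chain is reducible: state(s) %s unreachable",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("<promoter_model> D=%d%s, m_s=(%s), lam_s=(%s)\n", x$D,
              if (!is.null(x$kind)) paste0(" [", x$kind, "]") else "",
              paste(signif(x$m_s, 4), collapse = ", "),
              paste(signif(x$lam_s, 4), collapse = ", ")))
  invisible(x)
}
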