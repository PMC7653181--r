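#' Count lagged transitions between states
#'
#' Sliding-window transition counts within each trajectory's segment-label
#' sequence: `C[i, j]` is the number of positions `t` with `s(t) = i` and
#' `s(t + lag) = j`.  Windows never cross trajectory boundaries.
#' Trajectories shorter than `lag + 1` segments are skipped with a
#' warning.
#'
#' @param labels List of integer state sequences (one per trajectory), or
#'   a single vector.  States are 1-based.
#' @param lag Lag in segments (>= 1).
#' @param n_states Number of states (default: largest label observed).
#' @return Integer count matrix, `n_states` x `n_states`.
#' @export
count_transitions <- function(labels, lag = 1L, n_states = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  if (is.null(n_states)) n_states <- max(unlist(labels))
  C <- matrix(0L, n_states, n_states)
  for (s in labels) {
    n <- length(s)
    if (n < lag + 1L) {
      warning(sprintf("trajectory with %d segments is shorter than lag + 1 = %d; skipped",
                      n, lag + 1L))
      next
    }
    from <- s[seq_len(n - lag)]
    to <- s[seq_len(n - lag) + lag]
    tab <- table(factor(from, seq_len(n_states)),
                 factor(to, seq_len(n_states)))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  C
}

#' Row-stochastic transition matrix from counts
#'
#' Maximum-likelihood (row-normalized) estimate.  With
#' `reversible = TRUE` the symmetrized counts `(C + t(C)) / 2` are used
#' instead, which enforces detailed balance.
#'
#' @param counts Square non-negative count matrix.
#' @param reversible Symmetrize counts before normalizing.
#' @return Row-stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(counts, reversible = FALSE) {
  counts <- as.matrix(counts)
  if (reversible) counts <- (counts + t(counts)) / 2
  rs <- rowSums(counts)
  empty <- which(rs == 0)
  if (length(empty))
    stop("state(s) never visited as a transition source: ",
         paste(empty, collapse = ", "))
  counts / rs
}

# Communicating-class check by reachability on the positive-entry graph.
is_irreducible <- function(P) {
  n <- nrow(P)
  A <- P > 0
  R <- A | diag(TRUE, n)
  for (i in seq_len(ceiling(log2(n)) + 1L)) R <- (R %*% R) > 0
  all(R)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' The left eigenvector of eigenvalue 1, real, non-negative and
#' normalized to sum 1.  The chain must be irreducible (unique stationary
#' distribution).
#'
#' @param P Row-stochastic matrix.
#' @return Numeric vector summing to 1.
#' @export
#' @examples
#' stationary_distribution(matrix(c(0, 1, 1, 0), 2, 2))
stationary_distribution <- function(P) {
  P <- as.matrix(P)
  if (any(P < -1e-12) || max(abs(rowSums(P) - 1)) > 1e-8)
    stop("P is not row-stochastic")
  if (!is_irreducible(P))
    stop("chain is reducible: no unique stationary distribution")
  eg <- eigen(t(P))
  i <- which.min(abs(eg$values - 1))
  if (abs(eg$values[i] - 1) > 1e-8)
    stop("no unit eigenvalue found; P is not a valid stochastic matrix")
  v <- Re(eg$vectors[, i])
  v <- v / sum(v)
  if (min(v) < -1e-10)
    stop("stationary eigenvector has negative components")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' State lifetimes from the transition-matrix diagonal
#'
#' Under a geometric-exit model the mean dwell time of state `i` is
#' `lag_time / (1 - P[i, i])`; a diagonal of exactly 1 gives `Inf`.
#'
#' @param P Row-stochastic matrix.
#' @param lag_time Physical lag time (time units per counted lag).
#' @return Numeric vector of lifetimes in the units of `lag_time`.
#' @export
state_lifetimes <- function(P, lag_time = 1) {
  d <- diag(as.matrix(P))
  ifelse(d >= 1, Inf, lag_time / (1 - d))
}

#' Estimate a Markov model from discretized trajectories
#'
#' Convenience wrapper: counts lagged transitions, row-normalizes, and
#' derives the stationary distribution and state lifetimes.
#'
#' @inheritParams count_transitions
#' @inheritParams transition_matrix
#' @param lag_time Physical time per lag (e.g. `lag * L * dt`); defaults
#'   to `lag` (lifetimes in lag units).
#' @return A `markov_model`: `P`, `counts`, `lag`, `lag_time`,
#'   `stationary`, `lifetimes`.
#' @export
build_markov <- function(labels, lag = 1L, n_states = NULL,
                         lag_time = NULL, reversible = FALSE) {
  C <- count_transitions(labels, lag, n_states)
  P <- transition_matrix(C, reversible)
  if (is.null(lag_time)) lag_time <- lag
  structure(list(P = P, counts = C, lag = as.integer(lag),
                 lag_time = lag_time,
                 stationary = stationary_distribution(P),
                 lifetimes = state_lifetimes(P, lag_time)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model: %d states, lag = %d segment(s) (%g time units)>\n",
              nrow(x$P), x$lag, x$lag_time))
  cat("stationary:", sprintf("%.3f", x$stationary), "\n")
  cat("lifetimes :", sprintf("%.3g", x$lifetimes), "\n")
  invisible(x)
}
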