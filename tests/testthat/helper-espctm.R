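options(espctm.verbose = FALSE)

# small random trajectory with angles in [-pi, pi)
rand_traj <- function(n = 100, n_metrics = 2, dt = 0.1, id = "t",
                      energy = NULL) {
  m <- matrix(runif(n * n_metrics, -pi, pi), n, n_metrics)
  colnames(m) <- paste0("m", seq_len(n_metrics))
  metric_trajectory(m, energy %||% rnorm(n), dt = dt, id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# block similarity matrix: perfect within-block 1, between 0 (+ noise)
block_similarity <- function(sizes, noise = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  S <- outer(lab, lab, `==`) * 1
  if (noise > 0) {
    E <- matrix(rnorm(n * n, 0, noise), n, n)
    E <- (E + t(E)) / 2
    S <- S + E
    S[S > 1] <- 1
    S[S < -1] <- -1
  }
  diag(S) <- 1
  structure(S, class = c("similarity_matrix", "matrix"))
}

# same-partition check up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}

# direct discrete-transform low-pass oracle: brute-force DFT sums on the
# even-extended series, independent of the fft()-based implementation
lowpass_oracle <- function(e, K) {
  n <- length(e)
  ext <- c(e, rev(e))
  m <- 2 * n
  idx <- 0:(m - 1)
  co <- vapply(idx, function(k) sum(ext * exp(-1i * 2 * pi * k * idx / m)),
               complex(1))
  keep <- (idx < K) | ((m - idx) < K)
  out <- vapply(0:(n - 1), function(t)
    sum(co[keep] * exp(1i * 2 * pi * idx[keep] * t / m)) / m, complex(1))
  Re(out)
}
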