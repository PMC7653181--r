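#' Average projected trajectories over isometric segments
#'
#' Splits every projected trajectory into consecutive non-overlapping
#' windows of `L` frames and replaces each window by the average of its
#' projected vectors.  A trailing remainder shorter than `L` is dropped
#' (and logged): segments must be isometric.
#'
#' @param proj List of projected matrices (frames x `n_c`), one per
#'   trajectory, or a single matrix.
#' @param L Segment length in frames (>= 2, <= frames).
#' @param ids Trajectory identifiers (default `"traj1"`, ...).
#' @return A `segment_set`: `averages` (total segments x `n_c`),
#'   `provenance` (data frame: trajectory, start_frame), `L`,
#'   `n_segments` (per trajectory).
#' @export
segment_average <- function(proj, L, ids = NULL) {
  if (is.matrix(proj)) proj <- list(proj)
  L <- as.integer(L)
  if (L < 2L) stop("segment length L must be >= 2")
  if (is.null(ids)) ids <- paste0("traj", seq_along(proj))
  avgs <- list()
  prov <- list()
  nseg <- integer(length(proj))
  for (j in seq_along(proj)) {
    p <- as.matrix(proj[[j]])
    nf <- nrow(p)
    if (L > nf)
      stop(sprintf("segment length %d exceeds trajectory length %d", L, nf))
    ns <- nf %/% L
    nseg[j] <- ns
    drop_n <- nf - ns * L
    if (drop_n > 0L)
      esp_log("segment", "trajectory %s: dropping %d trailing frame(s)",
              ids[j], drop_n)
    grp <- rep(seq_len(ns), each = L)
    avgs[[j]] <- rowsum(p[seq_len(ns * L), , drop = FALSE], grp,
                        reorder = FALSE) / L
    prov[[j]] <- data.frame(trajectory = ids[j],
                            start_frame = (seq_len(ns) - 1L) * L + 1L)
  }
  structure(list(averages = do.call(rbind, avgs),
                 provenance = do.call(rbind, prov),
                 L = L, n_segments = nseg),
            class = "segment_set")
}

#' Segment-segment similarity matrix
#'
#' The similarity of two segments is the cosine of their average E-space
#' vectors augmented with one constant-1 component per dimension:
#' \deqn{S(t,t') = \frac{\sum_i [B_i(t) B_i(t') + 1]}
#'   {\sqrt{\sum_i [B_i(t)^2 + 1]\;\sum_i [B_i(t')^2 + 1]}}}
#' It is symmetric with unit diagonal and all entries in \[-1, 1\].
#'
#' @param segments A `segment_set` from [segment_average()], or a plain
#'   matrix of segment vectors.
#' @return A `similarity_matrix` (square numeric matrix).
#' @export
similarity_matrix <- function(segments) {
  B <- if (inherits(segments, "segment_set")) segments$averages
       else as.matrix(segments)
  if (nrow(B) < 2L) stop("need at least 2 segments")
  nc <- ncol(B)
  A <- tcrossprod(B) + nc
  d <- sqrt(diag(A))
  S <- A / outer(d, d)
  diag(S) <- 1
  structure(S, class = c("similarity_matrix", "matrix"))
}

# Row-stochastic normalization of a similarity matrix: negatives clipped
# to zero, rows normalized to sum 1.  Reversible w.r.t. the row sums, so
# its spectrum is real and computable through an equivalent symmetric
# matrix.
stochasticize <- function(S) {
  W <- unclass(S)
  W[W < 0] <- 0
  rs <- rowSums(W)
  zero <- which(rs <= 0)
  if (length(zero))
    stop("segment(s) with all-zero similarity row after clipping: ",
         paste(head(zero, 5), collapse = ", "))
  list(W = W, rs = rs)
}

# Real spectrum and right eigenvectors of the stochasticized similarity
# matrix T = D^{-1} W via the symmetric similarity transform
# D^{-1/2} W D^{-1/2}.
stochastic_eigen <- function(S, nvec = NULL) {
  st <- stochasticize(S)
  sq <- sqrt(st$rs)
  Tsym <- st$W / outer(sq, sq)
  eg <- eigen(Tsym, symmetric = TRUE)
  phi <- eg$vectors / sq # right eigenvectors of T
  list(values = eg$values, vectors = phi)
}

#' Choose the number of metastable states from the similarity spectrum
#'
#' Row-normalizes the (negativity-clipped) similarity matrix into a
#' stochastic matrix, computes its real eigenvalue spectrum in descending
#' order, and returns the position of the largest consecutive gap within
#' the leading eigenvalues (default: top 10).  An explicit `override`
#' wins.  With `gap_on_raw = TRUE` the gap is taken on the spectrum of the
#' raw similarity matrix instead.
#'
#' @param S A `similarity_matrix`.
#' @param override Optional integer forcing the state count.
#' @param top Number of leading eigenvalues searched for the gap.
#' @param gap_on_raw Use the raw similarity spectrum.
#' @return Integer state count, with the spectrum searched attached as
#'   attribute `"eigenvalues"`.
#' @export
select_n_states <- function(S, override = NULL, top = 10L,
                            gap_on_raw = FALSE) {
  ev <- if (gap_on_raw) sort(eigen(unclass(S), symmetric = TRUE,
                                   only.values = TRUE)$values,
                             decreasing = TRUE)
        else stochastic_eigen(S)$values
  m <- min(top, length(ev))
  lead <- ev[seq_len(m)]
  if (!is.null(override)) {
    ns <- as.integer(override)
  } else {
    gaps <- lead[-m] - lead[-1]
    ns <- which.max(gaps)
    esp_log("discretize", "eigen-gap at %d (top eigenvalues: %s)",
            ns, paste(sprintf("%.3f", lead[seq_len(min(6, m))]),
                      collapse = ", "))
  }
  attr(ns, "eigenvalues") <- lead
  ns
}

# PCCA+ membership construction: maps the simplex spanned by the dominant
# eigenvectors onto fuzzy memberships via the inner-simplex algorithm
# (pick the most spread-out rows as simplex vertices, invert).  Rows of
# the result sum to 1 exactly before clipping; small negative entries are
# clipped and rows renormalized.
pcca_memberships <- function(phi, n_states) {
  n <- nrow(phi)
  X <- cbind(1, phi[, 2:n_states, drop = FALSE])
  # vertex search by Gram-Schmidt deflation on rows
  idx <- integer(n_states)
  ortho <- X
  for (j in seq_len(n_states)) {
    norms <- rowSums(ortho^2)
    idx[j] <- which.max(norms)
    v <- ortho[idx[j], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12)
      stop("PCCA+ simplex construction failed: degenerate vertex (rank of ",
           "dominant eigenvectors < requested state count)")
    v <- v / nv
    ortho <- ortho - (ortho %*% v) %*% t(v)
  }
  A <- tryCatch(solve(X[idx, , drop = FALSE]),
                error = function(e)
                  stop("PCCA+ failed: vertex matrix is singular ",
                       "(states not distinguishable); diagnostics: idx = ",
                       paste(idx, collapse = ",")))
  chi <- X %*% A
  if (min(chi) < -0.2)
    esp_log("discretize",
            "PCCA+ memberships have entries as low as %.3f before clipping",
            min(chi))
  chi[chi < 0] <- 0
  chi / rowSums(chi)
}

#' Assign segments to metastable states by PCCA+
#'
#' Runs a robust Perron cluster analysis on the stochasticized similarity
#' matrix: the top `n_states` right eigenvectors are transformed by an
#' inner-simplex construction into non-negative fuzzy memberships summing
#' to one per segment; crisp labels are the membership argmax.  The
#' procedure is deterministic.
#'
#' @param S A `similarity_matrix`.
#' @param n_states Number of states, `2 <= n_states <= segments`.
#' @param provenance Optional provenance data frame (carried through from
#'   the `segment_set`).
#' @return A `state_assignment`: `n_states`, `labels` (1-based state per
#'   segment), `memberships` (segments x states), `eigenvalues`
#'   (descending spectrum of the stochasticized similarity matrix),
#'   `provenance`.
#' @export
assign_states <- function(S, n_states, provenance = NULL) {
  n_states <- as.integer(n_states)
  if (n_states < 2L || n_states > nrow(S))
    stop(sprintf("n_states = %d outside [2, %d]", n_states, nrow(S)))
  eg <- stochastic_eigen(S)
  # force the Perron eigenvector to the constant vector (exact for a
  # stochastic matrix; guards against degenerate leading eigenvalues)
  chi <- pcca_memberships(eg$vectors, n_states)
  labels <- max.col(chi, ties.method = "first")
  if (length(unique(labels)) < n_states)
    esp_log("discretize", "only %d of %d states received segments",
            length(unique(labels)), n_states)
  if (is.null(provenance))
    provenance <- data.frame(trajectory = "traj1",
                             start_frame = seq_len(nrow(S)))
  structure(list(n_states = n_states, labels = labels,
                 memberships = chi, eigenvalues = eg$values,
                 provenance = provenance),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("<state_assignment: %d segments -> %d states (%s)>\n",
              length(x$labels), x$n_states,
              paste(tabulate(x$labels, x$n_states), collapse = "/")))
  invisible(x)
}
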