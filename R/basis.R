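#' Build a sine/cosine basis set
#'
#' Constructs the basis \eqn{\{\sin(n\theta), \cos(n\theta)\}} over every
#' metric \eqn{\theta} and every integer multiplier \eqn{n = 1..max_n}.
#' The canonical ordering is: for each n (ascending), all sines of the
#' metrics in metric order, then all cosines, i.e.
#' `sin(1*m1), sin(1*m2), ..., cos(1*m1), cos(1*m2), ..., sin(2*m1), ...`.
#' That ordering defines column identity everywhere downstream (feature
#' matrices, regression weights, mapping operator rows).
#'
#' @param n_metrics Number of metric columns (>= 1).
#' @param max_n Largest multiplier (>= 1).
#' @return A `basis_set`: data frame with columns `kind` ("sin"/"cos"),
#'   `metric` (1-based metric index) and `n` (multiplier);
#'   `2 * n_metrics * max_n` rows.
#' @export
#' @examples
#' make_basis(2, 10)   # 40 basis functions for a 2-D particle
#' make_basis(10, 1)   # 40 for 10 dihedral-angle pairs, n = 1
make_basis <- function(n_metrics, max_n) {
  if (n_metrics < 1L) stop("n_metrics must be >= 1")
  if (max_n < 1L) stop("max_n must be >= 1")
  terms <- do.call(rbind, lapply(seq_len(max_n), function(n) {
    data.frame(kind = rep(c("sin", "cos"), each = n_metrics),
               metric = rep(seq_len(n_metrics), 2L),
               n = n)
  }))
  rownames(terms) <- NULL
  structure(terms, class = c("basis_set", "data.frame"))
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set: %d terms over %d metric(s), n up to %d>\n",
              nrow(x), max(x$metric), max(x$n)))
  invisible(x)
}

basis_labels <- function(basis) {
  sprintf("%s(%d*m%d)", basis$kind, basis$n, basis$metric)
}

#' Evaluate basis functions on a trajectory
#'
#' Maps every frame of a trajectory into the basis-function space: entry
#' (frame, term) is \eqn{\sin(n\theta)} or \eqn{\cos(n\theta)} of the
#' frame's metric \eqn{\theta}.  Raw values are bounded in \[-1, 1\] and
#' periodic in every metric.
#'
#' @param traj A [metric_trajectory()].
#' @param basis A `basis_set` from [make_basis()].
#' @return Numeric matrix, frames x terms (unnormalized).
#' @export
featurize <- function(traj, basis) {
  stopifnot(inherits(traj, "metric_trajectory"),
            inherits(basis, "basis_set"))
  if (max(basis$metric) > ncol(traj$metrics))
    stop(sprintf("basis refers to metric %d but trajectory has only %d",
                 max(basis$metric), ncol(traj$metrics)))
  out <- matrix(0, n_frames(traj), nrow(basis))
  for (j in seq_len(nrow(basis))) {
    ang <- basis$n[j] * traj$metrics[, basis$metric[j]]
    out[, j] <- if (basis$kind[j] == "sin") sin(ang) else cos(ang)
  }
  colnames(out) <- basis_labels(basis)
  out
}

#' Normalize feature matrices over the pooled dataset
#'
#' Z-scores every basis dimension using the mean and standard deviation of
#' the frames of *all* trajectories pooled together, then applies those
#' shared offsets and scales to each trajectory.  Pooled normalization is
#' required because the energy regression is performed on the joined
#' dataset.  Zero-variance (degenerate) columns are flagged and passed
#' through centered with scale 1 (so they become all-zero and naturally
#' receive zero regression weight) rather than dropped, keeping weight
#' vectors aligned with the basis.
#'
#' @param features List of raw feature matrices from [featurize()], all
#'   with the same column count.
#' @return List of class `feature_set`: `features` (list of normalized
#'   matrices), `center`, `scale` (per-column, scale 1 for degenerate
#'   columns), `degenerate` (logical per column).
#' @export
normalize_features <- function(features) {
  if (length(features) < 1L) stop("no feature matrices given")
  nb <- unique(vapply(features, ncol, integer(1)))
  if (length(nb) != 1L) stop("feature matrices differ in column count")
  n <- sum(vapply(features, nrow, integer(1)))
  csum <- Reduce(`+`, lapply(features, colSums))
  center <- csum / n
  css <- Reduce(`+`, lapply(features, function(f)
    colSums(sweep(f, 2L, center, `-`)^2)))
  sdev <- sqrt(css / (n - 1L))
  degenerate <- sdev < 1e-12 * pmax(abs(center), 1)
  scale <- ifelse(degenerate, 1, sdev)
  if (any(degenerate))
    esp_log("features", "%d degenerate (zero-variance) column(s) flagged",
            sum(degenerate))
  norm <- lapply(features, function(f) {
    out <- sweep(sweep(f, 2L, center, `-`), 2L, scale, `/`)
    colnames(out) <- colnames(f)
    out
  })
  structure(list(features = norm, center = center, scale = scale,
                 degenerate = degenerate),
            class = "feature_set")
}
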