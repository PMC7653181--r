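#' Fit the effective-energy rescaled orthogonal space (E-space)
#'
#' Rescales every feature column by its effective-energy regression weight
#' (`V %*% diag(weights)`), pools the frames of all trajectories, centers,
#' and eigen-decomposes the covariance matrix.  The mapping operator `M`
#' collects the leading eigenvectors; the retained count `N_c` is the
#' smallest number whose cumulative eigenvalue fraction reaches
#' `fraction` (default 0.90).  Eigenvector signs are fixed so that each
#' vector's largest-magnitude component is positive, making results
#' reproducible run to run.
#'
#' @param fset A `feature_set` from [normalize_features()] (or a plain
#'   list of feature matrices).
#' @param weights Numeric weight vector, one per basis column (the
#'   regression coefficients at the selected cutoff).
#' @param fraction Variance fraction to retain, in (0, 1].
#' @return An `espace` object: `weights`, `center` (of the weighted,
#'   pooled data), `M` (basis x `n_c` orthonormal mapping operator),
#'   `eigenvalues` (full descending spectrum), `n_c`,
#'   `fraction_retained`.
#' @export
fit_espace <- function(fset, weights, fraction = 0.90) {
  V <- if (inherits(fset, "feature_set")) fset$features else fset
  nb <- ncol(V[[1]])
  if (length(weights) != nb)
    stop(sprintf("weights length (%d) does not match basis size (%d)",
                 length(weights), nb))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- sum(vapply(V, nrow, integer(1)))
  if (n < 2L) stop("need at least 2 pooled frames")
  # Weighted pooled moments; covariance of V %*% diag(w) without forming
  # the pooled matrix.
  Sx <- Reduce(`+`, lapply(V, colSums)) * weights
  G <- Reduce(`+`, lapply(V, crossprod)) * outer(weights, weights)
  center <- Sx / n
  covm <- (G - outer(Sx, Sx) / n) / (n - 1L)
  eg <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  cumfrac <- cumsum(ev) / sum(ev)
  n_c <- which(cumfrac >= fraction - 1e-12)[1]
  M <- eg$vectors[, seq_len(n_c), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(n_c)) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  esp_log("espace", "retained N_c = %d of %d (%.1f%% of variance)",
          n_c, nb, 100 * cumfrac[n_c])
  structure(list(weights = weights, center = center, M = M,
                 eigenvalues = eg$values, n_c = n_c,
                 fraction_retained = cumfrac[n_c]),
            class = "espace")
}

#' @export
print.espace <- function(x, ...) {
  cat(sprintf("<espace: %d -> %d dimensions, %.1f%% variance retained>\n",
              length(x$weights), x$n_c, 100 * x$fraction_retained))
  invisible(x)
}

#' Project a feature matrix into the E-space
#'
#' Applies the same column weighting and centering used when fitting the
#' E-space, then the orthonormal mapping operator.  Deterministic given
#' the `espace` object.  Set `raw = TRUE` to project the unweighted
#' features through `M` instead (a literal-reading alternative kept for
#' comparison; the weighted projection is the default because `M` is
#' orthonormal in the weighted coordinates).
#'
#' @param features Numeric matrix (frames x basis terms).
#' @param espace An `espace` from [fit_espace()].
#' @param raw Project unweighted features if `TRUE`.
#' @return Numeric matrix, frames x `n_c`.
#' @export
project_espace <- function(features, espace, raw = FALSE) {
  stopifnot(inherits(espace, "espace"))
  features <- as.matrix(features)
  if (ncol(features) != length(espace$weights))
    stop(sprintf("feature column count (%d) does not match basis size (%d)",
                 ncol(features), length(espace$weights)))
  if (raw) return(features %*% espace$M)
  w <- sweep(features, 2L, espace$weights, `*`)
  sweep(w, 2L, espace$center, `-`) %*% espace$M
}
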