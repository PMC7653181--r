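#' Low-pass filter an energy series by FFT truncation
#'
#' Even-extends the series by mirroring (`c(e, rev(e))`, length 2N) to
#' suppress the boundary discontinuity, Fourier-transforms it, keeps only
#' the frequency indices `k = 0..K-1` on the extended grid (together with
#' their conjugate partners so the inverse stays real), inverse-transforms
#' and crops back to the original length.  `K = 1` keeps only the DC term
#' (the mean); the maximal `K = N + 1` keeps everything and reproduces the
#' input.  The physical cutoff frequency is `K / (2 N dt)`.
#'
#' @param energy Numeric vector, length >= 2.
#' @param K Integer cutoff, `1 <= K <= length(energy) + 1`.
#' @return Numeric vector of the same length as `energy`.
#' @export
lowpass_energy <- function(energy, K) {
  n <- length(energy)
  if (n < 2L) stop("energy series must have length >= 2")
  K <- as.integer(K)
  if (K < 1L || K > n + 1L)
    stop(sprintf("K = %d out of range [1, %d]", K, n + 1L))
  ext <- c(energy, rev(energy))
  co <- fft(ext)
  m <- 2L * n
  keep <- rep(FALSE, m)
  idx <- seq_len(K) # frequencies 0 .. K-1
  keep[idx] <- TRUE
  conj_idx <- m - (idx - 1L) + 1L # conjugate partners of k = 1..K-1
  keep[conj_idx[conj_idx <= m]] <- TRUE
  co[!keep] <- 0
  filt <- fft(co, inverse = TRUE) / m
  bad <- max(abs(Im(filt)))
  if (bad > 1e-8 * max(1, max(abs(Re(filt)))))
    stop("internal error: low-pass inverse transform is not real")
  Re(filt)[seq_len(n)]
}

# Minimum-norm least squares with intercept.  Returns a0, coefficients and
# the correlation measure r = 1 - mean(residual^2) / var_pop(target)
# (equivalently explained-variance fraction), with r = 0 when the target
# has zero variance.  Rank deficiency falls back to a pseudo-inverse
# (minimum-norm) solution and is logged.
ols_fit <- function(X, y) {
  n <- nrow(X)
  xbar <- colMeans(X)
  ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar, `-`)
  yc <- y - ybar
  sst <- sum(yc^2)
  if (sst <= 1e-14 * n * max(1, ybar^2))
    return(list(a0 = ybar, coef = rep(0, ncol(X)), r = 0,
                residual_variance = 0))
  G <- crossprod(Xc)
  b <- tryCatch(solve(G, crossprod(Xc, yc)),
                error = function(e) NULL)
  if (is.null(b)) {
    esp_log("regress", "rank-deficient design; using minimum-norm solution")
    eg <- eigen(G, symmetric = TRUE)
    pos <- eg$values > 1e-10 * max(eg$values, 0)
    b <- eg$vectors[, pos, drop = FALSE] %*%
      ((crossprod(eg$vectors[, pos, drop = FALSE], crossprod(Xc, yc))) /
         eg$values[pos])
  }
  b <- drop(b)
  ssr <- sum(b * crossprod(Xc, yc))
  r <- min(max(ssr / sst, 0), 1)
  list(a0 = ybar - sum(xbar * b), coef = b, r = r,
       residual_variance = max(sst - ssr, 0) / n)
}

#' Regress a low-passed energy onto basis features
#'
#' Ordinary least squares with intercept of the (pooled) low-passed energy
#' against the (pooled) normalized feature matrix, frame for frame.  The
#' multiple correlation coefficient is
#' \eqn{r = 1 - \overline{\epsilon^2} / \sigma^2} with \eqn{\sigma^2} the
#' population variance of the target, and \code{r = 0} by convention when the
#' target is constant.
#'
#' @param features Numeric matrix (pooled frames x basis terms).
#' @param target Numeric vector of pooled low-passed energies.
#' @return List with `a0` (intercept), `coef` (weight vector),
#'   `r` (in \[0, 1\]) and `residual_variance`.
#' @export
regress_energy <- function(features, target) {
  features <- as.matrix(features)
  if (nrow(features) != length(target))
    stop("features and target are not aligned frame-for-frame")
  if (nrow(features) < ncol(features) + 1L)
    warning(sprintf("only %d frames for %d features; regression is weakly determined",
                    nrow(features), ncol(features)))
  ols_fit(features, target)
}

#' Scan low-pass cutoffs and select the effective-energy model
#'
#' For every cutoff `K` in the scan range, low-pass filters each
#' trajectory's energy at `K` ([lowpass_energy()]), joins the filtered
#' energies and the normalized feature matrices of all trajectories, and
#' regresses the joined energy on the joined features.  The selected
#' cutoff `K*` maximizes the multiple correlation coefficient `r(K)` (ties
#' broken toward the smallest `K`, preferring the smoother energy), and
#' the effective energy of every frame is the fitted value
#' `a0 + features %*% coef` at `K*`.
#'
#' The scan uses a spectral shortcut: because the kept frequency set grows
#' one index at a time, the cross-products entering the normal equations
#' are cumulative sums over the energy spectrum (Parseval), so the cost
#' per additional `K` is one small linear solve rather than a fresh pass
#' over all frames.  The result is identical (to rounding) to filtering
#' and regressing from scratch at each `K`.
#'
#' @param fset A `feature_set` from [normalize_features()].
#' @param energies List of energy vectors, one per trajectory, all equal
#'   length (shared frequency grid).
#' @param k_range Integer vector of cutoffs to scan, e.g. `1:200`; default
#'   `1:floor(N/10)` with `N` the trajectory length.
#' @param dt Recording interval, used only to report physical cutoff
#'   frequencies.
#' @return An `effective_energy_model`: `k_star`, `r_curve` (data frame
#'   K / cutoff_frequency / r), `a0`, `coef`, `r`,
#'   `effective_energy` (list per trajectory), `lowpassed` (list per
#'   trajectory, filtered at `K*`), `residual_variance`.
#' @export
select_cutoff <- function(fset, energies, k_range = NULL, dt = 1) {
  stopifnot(inherits(fset, "feature_set"))
  V <- fset$features
  if (length(V) != length(energies))
    stop("feature and energy lists differ in length")
  n <- unique(vapply(energies, length, integer(1)))
  if (length(n) != 1L)
    stop("all trajectories must share one length (frequency grid)")
  if (any(vapply(V, nrow, integer(1)) != n))
    stop("feature matrices and energies are not aligned")
  if (is.null(k_range)) k_range <- seq_len(max(1L, n %/% 10L))
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty cutoff scan range")
  if (min(k_range) < 1L || max(k_range) > n + 1L)
    stop(sprintf("cutoff range outside [1, %d]", n + 1L))

  nb <- ncol(V[[1]])
  m <- 2L * n # even-extended length
  ntot <- as.numeric(n) * length(V)

  # Pooled feature moments (K-independent).
  Sx <- Reduce(`+`, lapply(V, colSums))
  G <- Reduce(`+`, lapply(V, crossprod))

  # Per-trajectory spectra: cross-spectrum of each (zero-padded) feature
  # column with the energy, and the energy power spectrum.  By Parseval,
  # partial sums over kept frequencies give sum_n x_n * yK_n and (using
  # the mirror symmetry of the filtered extension) sum_n yK_n^2 on the
  # first N frames.
  cross <- matrix(0, m, nb)
  power <- numeric(m)
  s_y <- 0
  for (j in seq_along(V)) {
    Fe <- fft(c(energies[[j]], rev(energies[[j]])))
    Fx <- mvfft(rbind(V[[j]], matrix(0, n, nb)))
    cross <- cross + Re(Conj(Fx) * Fe) / m
    power <- power + Abs2(Fe) / m
    s_y <- s_y + Re(Fe[1]) / 2
  }

  ks <- k_range
  r_vals <- numeric(length(ks))
  fits <- vector("list", length(ks))
  # cumulative sums in frequency order 0,1,...: increment for cutoff K
  # adds index q = K-1 and its conjugate partner.
  inc_idx <- function(q) {
    if (q == 0L || q == n) q + 1L else c(q + 1L, m - q + 1L)
  }
  xty <- rep(0, nb)
  yty <- 0
  q_done <- -1L
  for (i in seq_along(ks)) {
    K <- ks[i]
    while (q_done < K - 1L) {
      q_done <- q_done + 1L
      ii <- inc_idx(q_done)
      xty <- xty + colSums(cross[ii, , drop = FALSE])
      yty <- yty + sum(power[ii]) / 2
    }
    ybar <- s_y / ntot
    xty_c <- xty - Sx * ybar
    sst <- yty - s_y^2 / ntot
    if (sst <= 1e-12 * max(1, ybar^2) * ntot) {
      fits[[i]] <- list(a0 = ybar, coef = rep(0, nb), r = 0)
      r_vals[i] <- 0
      next
    }
    Gc <- G - outer(Sx, Sx) / ntot
    b <- tryCatch(drop(solve(Gc, xty_c)), error = function(e) NULL)
    if (is.null(b)) {
      eg <- eigen(Gc, symmetric = TRUE)
      pos <- eg$values > 1e-10 * max(eg$values, 0)
      b <- drop(eg$vectors[, pos, drop = FALSE] %*%
                  (crossprod(eg$vectors[, pos, drop = FALSE], xty_c) /
                     eg$values[pos]))
    }
    ssr <- sum(b * xty_c)
    r_vals[i] <- min(max(ssr / sst, 0), 1)
    fits[[i]] <- list(a0 = ybar - sum((Sx / ntot) * b), coef = b,
                      r = r_vals[i],
                      residual_variance = max(sst - ssr, 0) / ntot)
  }

  best <- min(ks[r_vals >= max(r_vals) - 1e-12])
  ib <- match(best, ks)
  fit <- fits[[ib]]
  eff <- lapply(V, function(v) fit$a0 + drop(v %*% fit$coef))
  lp <- lapply(energies, lowpass_energy, K = best)
  esp_log("energy", "K* = %d (cutoff %.4g per time unit), r = %.4f",
          best, best / (m * dt), r_vals[ib])
  structure(list(
    k_star = best,
    r_curve = data.frame(K = ks, cutoff_frequency = ks / (m * dt),
                         r = r_vals),
    a0 = fit$a0, coef = fit$coef, r = r_vals[ib],
    residual_variance = fit$residual_variance,
    effective_energy = eff, lowpassed = lp),
    class = "effective_energy_model")
}

Abs2 <- function(z) Re(z)^2 + Im(z)^2

#' @export
print.effective_energy_model <- function(x, ...) {
  cat(sprintf(
    "<effective_energy_model: K* = %d, r = %.4f, %d weights, %d trajectories>\n",
    x$k_star, x$r, length(x$coef), length(x$effective_energy)))
  invisible(x)
}
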