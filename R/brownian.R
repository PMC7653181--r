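#' Three-well landscape potential and gradient
#'
#' The toy landscape is
#' \deqn{U(x, y) = -\epsilon\{\cos x + \sin x + \tfrac12\cos y +
#'   2\cos 3x + 2\exp[-20 (x + 2\pi/3)^2 - 2 y^2]\}}
#' treated as periodic on \eqn{[-\pi, \pi)^2}: the Gaussian basin term
#' uses periodically wrapped displacements, so every cell carries the same
#' three wells and the Boltzmann measure on the torus is well defined.
#' Along `y = 0` the landscape has three minima (left to right: S0 —
#' narrow, created by the Gaussian term; S1 — the deepest; S2), with the
#' barrier between S0 and S1 much higher than between S1 and S2.
#'
#' @param x,y Coordinates (any shape, recycled).
#' @param eps Scaling parameter of the landscape (default 40).
#' @return `three_well_potential`: potential values; `three_well_gradient`:
#'   a 2-column matrix of \eqn{(\partial_x U, \partial_y U)}.
#' @export
three_well_potential <- function(x, y, eps = 40) {
  bx <- wrap_angle(x + 2 * pi / 3)
  by <- wrap_angle(y)
  g <- exp(-20 * bx^2 - 2 * by^2)
  -eps * (cos(x) + sin(x) + 0.5 * cos(y) + 2 * cos(3 * x) + 2 * g)
}

#' @rdname three_well_potential
#' @export
three_well_gradient <- function(x, y, eps = 40) {
  gradient_cpp(as.numeric(x), as.numeric(y), eps)
}

wrap_angle <- function(z) z - 2 * pi * floor((z + pi) / (2 * pi))

# Locate the three minima (cached per eps).
minima_cache <- new.env(parent = emptyenv())

#' Minima of the three-well landscape
#'
#' @param eps Landscape scale.
#' @return Matrix 3 x 2 of (x, y) minima ordered by x (S0, S1, S2).
#' @export
find_basin_minima <- function(eps = 40) {
  key <- sprintf("%.12g", eps)
  if (!is.null(minima_cache[[key]])) return(minima_cache[[key]])
  starts <- rbind(c(-2 * pi / 3, 0), c(0.05, 0), c(2, 0))
  mins <- t(apply(starts, 1, function(s) {
    # fixed-step steepest descent first: BFGS alone can overshoot the
    # narrow Gaussian well and escape to a periodic image
    p <- s
    for (i in seq_len(5000)) {
      g <- drop(three_well_gradient(p[1], p[2], eps))
      p <- p - 2e-4 * g
      if (sum(g^2) < 1e-16) break
    }
    op <- optim(p, function(q) three_well_potential(q[1], q[2], eps),
                function(q) drop(three_well_gradient(q[1], q[2], eps)),
                method = "BFGS", control = list(reltol = 1e-14))
    wrap_angle(op$par)
  }))
  mins <- mins[order(mins[, 1]), , drop = FALSE]
  colnames(mins) <- c("x", "y")
  minima_cache[[key]] <- mins
  mins
}

#' Assign points to potential basins by steepest descent
#'
#' Watershed partition: every point belongs to the minimum its steepest-
#' descent path reaches (with periodic wrapping).
#'
#' @param x,y Coordinates.
#' @param eps Landscape scale.
#' @param step Descent step size.
#' @param maxit Maximum descent iterations.
#' @return Integer basin labels, 1 = S0 (leftmost) to 3 = S2.
#' @export
assign_basins <- function(x, y, eps = 40, step = 5e-4, maxit = 20000L) {
  mins <- find_basin_minima(eps)
  lab <- descend_basins_cpp(as.numeric(x), as.numeric(y), eps,
                            mins[, 1], mins[, 2], step, maxit, 0.25)
  if (anyNA(lab)) {
    # points stuck exactly on a separatrix ridge (zero-gradient lines,
    # measure zero): tie-break by nearest minimum on the torus
    bad <- which(is.na(lab))
    d <- sapply(seq_len(nrow(mins)), function(m)
      wrap_angle(x[bad] - mins[m, 1])^2 + wrap_angle(y[bad] - mins[m, 2])^2)
    lab[bad] <- max.col(-matrix(d, nrow = length(bad)))
    esp_log("basins", "%d separatrix point(s) assigned by nearest minimum",
            length(bad))
  }
  lab
}

#' Simulate Brownian-particle trajectories on the three-well landscape
#'
#' Integrates the underdamped Langevin equation
#' \eqn{m \dot v = -\nabla U - \gamma v + \xi(t)} with delta-correlated
#' zero-mean Gaussian noise obeying fluctuation-dissipation, using the
#' BAOAB splitting.  Positions (wrapped to \eqn{[-\pi,\pi)}) are recorded
#' every `stride` steps; the recorded energy is the instantaneous
#' potential plus independent Gaussian measurement noise of standard
#' deviation `energy_noise` (emulating the energy fluctuation of the
#' unresolved environment).  Fully reproducible from `seed`.
#'
#' @param n_traj Number of trajectories.
#' @param n_frames Frames to record per trajectory.
#' @param eps Landscape scale.
#' @param kT Thermal energy (same units as the potential).  The default
#'   is the temperature calibrated against the published equilibrium
#'   distribution of this landscape (see [calibrate_temperature()]).
#' @param mass,gamma Particle mass and friction coefficient.
#' @param dt Integration timestep.
#' @param stride Record every `stride`-th step (recording interval
#'   `dt * stride`).
#' @param energy_noise Standard deviation of the Gaussian noise added to
#'   recorded energies (default `5 * eps`).  The default is deliberately
#'   large: it emulates the regime the energy filter is designed for, in
#'   which the fluctuation of the unresolved environment conceals the
#'   landscape's slow energy signal in the raw per-frame series.
#' @param equil Equilibration steps discarded before recording (the
#'   default, 100 time units, is several times the longest basin
#'   lifetime, so the recorded series starts near equilibrium even from
#'   uniform random initial positions).
#' @param starts `"random"` (uniform on the torus) or a matrix `n_traj x
#'   2` of starting positions.
#' @param seed Random seed; `NULL` leaves the RNG state alone.
#' @return List of [metric_trajectory()] objects with metrics `x`, `y`
#'   and recording interval `dt * stride`.
#' @export
simulate_brownian <- function(n_traj = 10L, n_frames = 10000L, eps = 40,
                              kT = 60, mass = 1, gamma = 1, dt = 0.002,
                              stride = 50L, energy_noise = 5 * eps,
                              equil = 50000L, starts = "random",
                              seed = NULL) {
  stopifnot(n_traj >= 1L, n_frames >= 2L, eps > 0, kT >= 0, mass > 0,
            gamma > 0, dt > 0, stride >= 1L, energy_noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.character(starts) && identical(starts, "random")) {
    starts <- cbind(runif(n_traj, -pi, pi), runif(n_traj, -pi, pi))
  } else {
    starts <- as.matrix(starts)
    if (nrow(starts) != n_traj || ncol(starts) != 2L)
      stop("starts must be 'random' or an n_traj x 2 matrix")
  }
  out <- vector("list", n_traj)
  for (j in seq_len(n_traj)) {
    v0 <- if (kT > 0) rnorm(2, 0, sqrt(kT / mass)) else c(0, 0)
    rec <- langevin_cpp(starts[j, 1], starts[j, 2], v0[1], v0[2],
                        as.integer(equil), as.integer(n_frames) * stride,
                        as.integer(stride), dt, mass, gamma, kT, eps,
                        energy_noise, 0L, 0)
    colnames(rec) <- c("x", "y", "energy")
    out[[j]] <- metric_trajectory(rec[, 1:2], rec[, 3], dt = dt * stride,
                                  id = sprintf("traj%02d", j))
  }
  esp_log("simulate", "%d trajectories x %d frames (kT = %g, eps = %g)",
          n_traj, n_frames, kT, eps)
  out
}

#' Simulate in a harmonic well (integrator test hook)
#'
#' Same integrator on an isotropic harmonic potential
#' `U = k/2 (x^2 + y^2)`; at equilibrium each coordinate has variance
#' `kT / k` (equipartition), which exercises the thermostat independently
#' of the landscape.
#'
#' @inheritParams simulate_brownian
#' @param k_spring Spring constant.
#' @return A single [metric_trajectory()].
#' @export
simulate_harmonic <- function(n_frames = 10000L, k_spring = 1, kT = 1,
                              mass = 1, gamma = 1, dt = 0.01,
                              stride = 5L, energy_noise = 0,
                              equil = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v0 <- if (kT > 0) rnorm(2, 0, sqrt(kT / mass)) else c(0, 0)
  rec <- langevin_cpp(0, 0, v0[1], v0[2], as.integer(equil),
                      as.integer(n_frames) * stride, as.integer(stride),
                      dt, mass, gamma, kT, 1, energy_noise, 1L, k_spring)
  colnames(rec) <- c("x", "y", "energy")
  metric_trajectory(rec[, 1:2], rec[, 3], dt = dt * stride,
                    id = "harmonic")
}

# Shared quadrature grid + watershed partition for the Boltzmann oracle.
basin_grid <- function(eps, n_grid) {
  # cell-centered (midpoint) grid: no point sits exactly on the periodic
  # boundary or the zero-gradient ridge lines
  gx <- -pi + (seq_len(n_grid) - 0.5) * (2 * pi / n_grid)
  gy <- gx
  G <- expand.grid(x = gx, y = gy)
  lab <- assign_basins(G$x, G$y, eps)
  list(x = G$x, y = G$y, lab = lab,
       U = three_well_potential(G$x, G$y, eps))
}

#' Boltzmann equilibrium weights of the three basins
#'
#' Numerically integrates \eqn{e^{-U/kT}} on a regular grid over one
#' periodic cell \eqn{[-\pi,\pi)^2}, partitioning grid points into basins
#' by steepest descent, and normalizes the per-basin sums.  A convergence
#' check repeats the quadrature at 1.5x resolution and errors if any
#' weight moves by more than `tol`.
#'
#' @param eps Landscape scale.
#' @param kT Thermal energy.
#' @param n_grid Grid points per axis (default 240).
#' @param tol Convergence tolerance between the two resolutions.
#' @return Numeric vector of length 3 (weights of S0, S1, S2, summing
#'   to 1).
#' @export
boltzmann_basin_weights <- function(eps = 40, kT = 60, n_grid = 240L,
                                    tol = 1e-3) {
  stopifnot(kT > 0)
  w <- function(g) {
    dens <- exp(-(g$U - min(g$U)) / kT)
    ws <- vapply(1:3, function(b) sum(dens[g$lab == b]), numeric(1))
    ws / sum(ws)
  }
  w1 <- w(basin_grid(eps, as.integer(n_grid)))
  w2 <- w(basin_grid(eps, as.integer(round(n_grid * 1.5))))
  if (max(abs(w1 - w2)) > tol)
    stop(sprintf("quadrature not converged: max weight change %.2g > %.2g; increase n_grid",
                 max(abs(w1 - w2)), tol))
  names(w2) <- c("S0", "S1", "S2")
  w2
}

#' Calibrate the simulation temperature against target basin weights
#'
#' The published equilibrium distribution of the three-well system does
#' not come with a printed temperature; this helper scans kT and reports
#' the value whose Boltzmann basin weights are closest (least squares) to
#' the target.  The returned temperature is the package's default for
#' [simulate_brownian()].
#'
#' @param target Target weights (default: the published equilibrium
#'   distribution 0.186, 0.538, 0.276 for S0, S1, S2).
#' @param eps Landscape scale.
#' @param interval Search interval for kT.
#' @param n_grid Quadrature resolution.
#' @return List: `kT` (the minimizer), `weights` (at that kT),
#'   `distance` (Euclidean distance to target).
#' @export
calibrate_temperature <- function(target = c(0.186, 0.538, 0.276),
                                  eps = 40, interval = c(5, 200),
                                  n_grid = 240L) {
  g <- basin_grid(eps, as.integer(n_grid))
  wfun <- function(kT) {
    dens <- exp(-(g$U - min(g$U)) / kT)
    ws <- vapply(1:3, function(b) sum(dens[g$lab == b]), numeric(1))
    ws / sum(ws)
  }
  op <- optimize(function(kT) sum((wfun(kT) - target)^2), interval)
  ws <- wfun(op$minimum)
  names(ws) <- c("S0", "S1", "S2")
  list(kT = op$minimum, weights = ws, distance = sqrt(op$objective))
}
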