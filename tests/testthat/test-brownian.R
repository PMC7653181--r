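test_that("landscape potential evaluates exactly and is symmetric in y", {
  # at the origin with eps = 1: -(1 + 0 + 1/2 + 2) minus a vanishing
  # Gaussian term
  expect_equal(three_well_potential(0, 0, eps = 1), -3.5,
               tolerance = 1e-6)
  set.seed(20)
  x <- runif(200, -pi, pi)
  y <- runif(200, -pi, pi)
  expect_equal(three_well_potential(x, y), three_well_potential(x, -y))
  # periodic continuation
  expect_equal(three_well_potential(x + 2 * pi, y - 2 * pi),
               three_well_potential(x, y), tolerance = 1e-10)
  # R and compiled implementations agree
  expect_equal(three_well_potential(x, y),
               vapply(seq_along(x), function(i)
                 potential_cpp(x[i], y[i], 40), numeric(1)))
})

test_that("closed-form gradient matches central finite differences", {
  set.seed(21)
  x <- runif(100, -3, 3)
  y <- runif(100, -3, 3)
  g <- three_well_gradient(x, y)
  h <- 1e-6
  gx <- (three_well_potential(x + h, y) - three_well_potential(x - h, y)) / (2 * h)
  gy <- (three_well_potential(x, y + h) - three_well_potential(x, y - h)) / (2 * h)
  expect_equal(g[, 1], gx, tolerance = 1e-5)
  expect_equal(g[, 2], gy, tolerance = 1e-5)
})

test_that("three minima are located and partition the cell into basins", {
  mins <- find_basin_minima(40)
  expect_equal(dim(mins), c(3L, 2L))
  # S1 (middle) is the deepest well; S0 sits at the Gaussian basin
  U <- three_well_potential(mins[, 1], mins[, 2])
  expect_true(which.min(U) == 2)
  expect_equal(unname(mins[1, 1]), -2 * pi / 3, tolerance = 0.05)
  expect_equal(unname(mins[, 2]), rep(0, 3), tolerance = 1e-4)
  # gradient vanishes at the minima
  expect_lt(max(abs(three_well_gradient(mins[, 1], mins[, 2]))), 1e-4)
  # each minimum is assigned to its own basin
  expect_equal(assign_basins(mins[, 1], mins[, 2]), 1:3)
})

test_that("simulation is reproducible and respects limiting regimes", {
  t1 <- simulate_brownian(n_traj = 2, n_frames = 50, equil = 100, seed = 42)
  t2 <- simulate_brownian(n_traj = 2, n_frames = 50, equil = 100, seed = 42)
  expect_identical(t1[[1]]$metrics, t2[[1]]$metrics)
  expect_identical(t1[[2]]$energy, t2[[2]]$energy)

  # zero temperature, zero energy noise, started at a minimum: the
  # particle stays and the recorded energy is constant
  mins <- find_basin_minima(40)
  tz <- simulate_brownian(n_traj = 1, n_frames = 50, kT = 0,
                          energy_noise = 0, equil = 0,
                          starts = mins[2, , drop = FALSE], seed = 1)[[1]]
  expect_lt(max(abs(tz$metrics[, 1] - mins[2, 1])), 1e-6)
  expect_lt(diff(range(tz$energy)), 1e-6)
})

test_that("thermostat reproduces equipartition in a harmonic well", {
  tr <- simulate_harmonic(n_frames = 50000, k_spring = 2, kT = 1.5,
                          stride = 20, seed = 23)
  expect_equal(var(tr$metrics[, 1]), 1.5 / 2, tolerance = 0.05)
  expect_equal(var(tr$metrics[, 2]), 1.5 / 2, tolerance = 0.05)
  expect_equal(mean(tr$metrics), 0, tolerance = 0.05)
})

test_that("trajectories at the working temperature populate all three wells", {
  trajs <- simulate_brownian(n_traj = 2, n_frames = 3000, seed = 31)
  lab <- unlist(lapply(trajs, function(t)
    assign_basins(t$metrics[, 1], t$metrics[, 2])))
  occ <- tabulate(lab, 3) / length(lab)
  expect_true(all(occ > 0.03))
  expect_equal(sum(occ), 1)
})

test_that("Boltzmann quadrature agrees with Monte Carlo and orders the wells", {
  kT <- 60
  w <- boltzmann_basin_weights(40, kT)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # published ordering of the equilibrium weights: S1 > S2 > S0
  expect_true(w["S1"] > w["S2"] && w["S2"] > w["S0"])

  # Monte Carlo importance oracle with jackknife standard errors
  set.seed(24)
  n <- 2e5
  x <- runif(n, -pi, pi)
  y <- runif(n, -pi, pi)
  dens <- exp(-(three_well_potential(x, y) + 160) / kT)
  lab <- assign_basins(x, y)
  est <- tapply(dens, factor(lab, 1:3), sum)
  est <- est / sum(est)
  blk <- rep(1:20, length.out = n)
  bs <- sapply(1:20, function(b) {
    v <- tapply(dens[blk == b], factor(lab[blk == b], 1:3), sum)
    v / sum(v)
  })
  se <- apply(bs, 1, sd) / sqrt(20)
  expect_true(all(abs(w - est) < 3 * pmax(se, 1e-4)))

  # coarse grids fail the convergence check
  expect_error(boltzmann_basin_weights(40, kT, n_grid = 12, tol = 1e-5),
               "not converged")
})

test_that("temperature calibration finds an interior optimum", {
  cal <- calibrate_temperature(n_grid = 160)
  expect_gt(cal$kT, 20)
  expect_lt(cal$kT, 150)
  expect_true(cal$weights["S1"] > cal$weights["S2"] &&
                cal$weights["S2"] > cal$weights["S0"])
  expect_lt(cal$distance, 0.1)
})
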