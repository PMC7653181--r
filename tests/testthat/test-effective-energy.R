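test_that("low-pass filter keeps constants, round-trips at full K, and matches a direct DFT oracle", {
  # constant series: only the DC term is nonzero
  expect_equal(lowpass_energy(rep(3.7, 50), 1), rep(3.7, 50))
  expect_equal(lowpass_energy(rep(3.7, 50), 20), rep(3.7, 50))

  set.seed(5)
  e <- rnorm(64)
  # maximal K keeps everything
  expect_equal(lowpass_energy(e, 65), e, tolerance = 1e-10)
  # brute-force DFT summation oracle at several cutoffs
  for (K in c(1, 2, 5, 13, 33)) {
    expect_equal(lowpass_energy(e, K), lowpass_oracle(e, K),
                 tolerance = 1e-9)
  }
  expect_error(lowpass_energy(e, 0), "out of range")
  expect_error(lowpass_energy(e, 66), "out of range")
})

test_that("low-pass filter separates frequencies around the cutoff", {
  # cosine with 5 full periods over the even-extended series (frequency
  # index 5 on the extended grid)
  n <- 100
  x <- cos(pi * 5 * (seq_len(n) - 0.5) / n)
  lo <- lowpass_energy(x, 5) # excludes it
  hi <- lowpass_energy(x, 7) # includes it
  expect_lt(max(abs(lo - mean(x))), 0.05)
  expect_lt(max(abs(hi - x)), 0.05)
})

test_that("low-pass filter is linear and idempotent", {
  set.seed(6)
  a <- rnorm(80)
  b <- rnorm(80)
  K <- 9
  expect_equal(lowpass_energy(2 * a - 3 * b, K),
               2 * lowpass_energy(a, K) - 3 * lowpass_energy(b, K),
               tolerance = 1e-10)
  la <- lowpass_energy(a, K)
  expect_equal(lowpass_energy(la, K), la, tolerance = 1e-8)
})

test_that("even extension suppresses boundary artifacts on a linear ramp", {
  n <- 200
  ramp <- seq(0, 1, length.out = n)
  f <- lowpass_energy(ramp, 20)
  interior <- 11:(n - 10)
  expect_lt(max(f[interior]) - 1, 0.02)
  expect_gt(min(f[interior]), -0.02)
  expect_lt(max(abs(f[interior] - ramp[interior])), 0.02)
})

test_that("regression recovers exact linear targets and returns r in [0, 1]", {
  set.seed(8)
  X <- matrix(rnorm(600), 200, 3)
  y <- 2 + 1.5 * X[, 1] - 0.7 * X[, 3]
  fit <- regress_energy(X, y)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  expect_equal(fit$coef, c(1.5, 0, -0.7), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$a0, 2, tolerance = 1e-8)

  # pure noise, large sample: r near zero (E[r] = p/n under the null)
  y2 <- rnorm(2000)
  X2 <- matrix(rnorm(2000 * 3), 2000, 3)
  expect_lt(regress_energy(X2, y2)$r, 0.02)

  # constant target: r = 0 by convention
  expect_equal(regress_energy(X, rep(4, 200))$r, 0)

  # r bounded for arbitrary targets
  for (i in 1:5) {
    r <- regress_energy(X, rnorm(200, sd = 10^runif(1, -3, 3)))$r
    expect_gte(r, 0)
    expect_lte(r, 1)
  }

  # rank-deficient design: minimum-norm solution, no crash
  Xd <- cbind(X, X[, 1])
  fit <- regress_energy(Xd, y)
  expect_equal(fit$r, 1, tolerance = 1e-8)
})

test_that("cutoff scan equals the direct filter-then-regress route", {
  set.seed(9)
  b <- make_basis(2, 2)
  trajs <- lapply(1:2, function(i) rand_traj(64, 2, id = paste0("t", i)))
  fset <- normalize_features(lapply(trajs, featurize, basis = b))
  energies <- lapply(trajs, function(t) t$energy)
  em <- select_cutoff(fset, energies, k_range = 1:20, dt = 1)
  Xp <- do.call(rbind, fset$features)
  for (K in c(1, 3, 7, 15, 20)) {
    yp <- unlist(lapply(energies, lowpass_energy, K = K))
    direct <- regress_energy(Xp, yp)
    expect_equal(em$r_curve$r[em$r_curve$K == K], direct$r,
                 tolerance = 1e-8)
  }
  # effective energy is exactly the fitted values at K*
  eff <- lapply(fset$features,
                function(v) em$a0 + drop(v %*% em$coef))
  expect_equal(em$effective_energy, eff, tolerance = 1e-12)
  expect_true(all(em$r_curve$r >= 0 & em$r_curve$r <= 1))
})

test_that("cutoff selection recovers a known bandwidth and weights", {
  # target linear in the slow (band-limited, frequencies 1..3) parts of
  # the features, which are themselves measured with white jitter, plus
  # strong white target noise; per-band power increases toward the band
  # edge, so r(K) rises until the whole band is included and falls once
  # further cutoffs only admit noise
  n <- 256
  amp <- c(0.7, 1.4, 2.8)
  truth <- c(0.8, 1, 1.25)
  hits <- 0
  coss <- numeric(0)
  for (seed in 1:20) {
    set.seed(seed)
    tgrid <- (seq_len(n) - 0.5) / n
    modes <- sapply(1:3, function(k) amp[k] * cos(pi * k * tgrid))
    X <- modes + matrix(rnorm(n * 3, sd = 0.3), n, 3)
    y <- drop(modes %*% truth) + rnorm(n, sd = 4)
    fset <- structure(list(features = list(X)), class = "feature_set")
    em <- select_cutoff(fset, list(y), k_range = 1:40, dt = 1)
    if (em$k_star >= 4 && em$k_star <= 8) hits <- hits + 1
    coss <- c(coss, sum(em$coef * truth) /
                sqrt(sum(em$coef^2) * sum(truth^2)))
  }
  expect_gte(hits, 16)
  expect_gt(mean(coss), 0.95)
  expect_true(all(coss > 0.85))
})

test_that("tie-break at equal r prefers the smallest cutoff", {
  # noiseless target linear in band-limited features: r(K) = 1 for every
  # K at or above the bandwidth
  n <- 128
  tgrid <- (seq_len(n) - 0.5) / n
  X <- sapply(1:2, function(k) cos(pi * k * tgrid))
  y <- drop(X %*% c(1, 2))
  fset <- structure(list(features = list(X)), class = "feature_set")
  em <- select_cutoff(fset, list(y), k_range = 1:20, dt = 1)
  expect_equal(em$r, 1, tolerance = 1e-8)
  first_one <- min(em$r_curve$K[em$r_curve$r >= 1 - 1e-9])
  expect_equal(em$k_star, first_one)
  expect_lte(em$k_star, 4)
})
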