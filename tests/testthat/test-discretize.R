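test_that("segment averaging makes isometric pieces and drops remainders", {
  # 20,000 frames cut into 100 pieces -> 200 frames per piece
  p <- matrix(rnorm(20000 * 2), 20000, 2)
  segs <- segment_average(list(p), L = 200)
  expect_equal(nrow(segs$averages), 100L)
  expect_equal(segs$averages[1, ], colMeans(p[1:200, ]))
  expect_equal(segs$averages[100, ], colMeans(p[19801:20000, ]))

  # 50 trajectories x 100 pieces -> 5,000 segment vectors
  many <- replicate(50, matrix(rnorm(400 * 2), 400, 2), simplify = FALSE)
  expect_equal(nrow(segment_average(many, L = 4)$averages), 5000L)

  # constant trajectory: every average equals the constant
  const <- matrix(2.5, 30, 3)
  expect_true(all(segment_average(list(const), L = 7)$averages == 2.5))

  # remainder dropped; too-long L errors
  segs2 <- segment_average(list(matrix(1:50, 25, 2)), L = 10)
  expect_equal(nrow(segs2$averages), 2L)
  expect_error(segment_average(list(matrix(0, 5, 1)), L = 10), "exceeds")
  expect_error(segment_average(list(matrix(0, 5, 1)), L = 1), ">= 2")
})

test_that("similarity matrix matches the augmented-cosine definition", {
  # hand evaluation: N_c = 2, B = (1,0), B' = (0,1) -> 2 / sqrt(3 * 3)
  S <- similarity_matrix(rbind(c(1, 0), c(0, 1)))
  expect_equal(S[1, 2], 2 / 3, tolerance = 1e-15)
  expect_equal(diag(S), c(1, 1))

  # identical segments and zero vectors give exactly 1
  S2 <- similarity_matrix(rbind(c(0.3, -1), c(0.3, -1), c(0, 0), c(0, 0)))
  expect_equal(S2[1, 2], 1)
  expect_equal(S2[3, 4], 1)

  # brute-force double-loop oracle on random segments
  set.seed(14)
  B <- matrix(rnorm(40 * 3, sd = 2), 40, 3)
  S3 <- similarity_matrix(B)
  nc <- ncol(B)
  for (t in sample(40, 6)) {
    for (u in sample(40, 6)) {
      num <- sum(B[t, ] * B[u, ] + 1)
      den <- sqrt(sum(B[t, ]^2 + 1) * sum(B[u, ]^2 + 1))
      expect_equal(S3[t, u], num / den, tolerance = 1e-12)
    }
  }
  expect_true(all(abs(S3) <= 1 + 1e-12))
  expect_equal(S3, t(S3), tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("state count comes from the leading eigenvalue gap", {
  S3 <- block_similarity(c(5, 7, 6))
  ns <- select_n_states(S3)
  expect_equal(as.integer(ns), 3L)
  ev <- attr(ns, "eigenvalues")
  expect_equal(ev[1:3], rep(1, 3), tolerance = 1e-10)
  expect_lt(ev[4], 0.5)

  S2 <- block_similarity(c(8, 8))
  ns2 <- select_n_states(S2)
  expect_equal(as.integer(ns2), 2L)
  expect_equal(attr(ns2, "eigenvalues")[1:2], c(1, 1), tolerance = 1e-10)

  # override wins
  expect_equal(as.integer(select_n_states(S3, override = 5)), 5L)
})

test_that("PCCA+ recovers separable blocks exactly", {
  S <- block_similarity(c(6, 4, 5))
  truth <- rep(1:3, c(6, 4, 5))
  a <- assign_states(S, 3)
  expect_true(same_partition(a$labels, truth))
  expect_lt(max(abs(a$memberships - round(a$memberships))), 1e-6)
  expect_equal(rowSums(a$memberships), rep(1, 15), tolerance = 1e-8)
  expect_equal(a$labels, max.col(a$memberships))
})

test_that("PCCA+ is robust to noise on the block structure", {
  ok <- 0
  for (seed in 1:10) {
    set.seed(seed)
    S <- block_similarity(c(20, 15), noise = 0.05)
    truth <- rep(1:2, c(20, 15))
    a <- assign_states(S, 2)
    acc <- max(mean(a$labels == truth), mean(a$labels == 3 - truth))
    if (acc >= 0.99) ok <- ok + 1
    expect_true(all(a$memberships >= 0))
    expect_equal(rowSums(a$memberships), rep(1, 35), tolerance = 1e-8)
  }
  expect_gte(ok, 10)
})

test_that("downstream quantities are invariant under segment permutation", {
  set.seed(15)
  S <- block_similarity(c(8, 6, 7), noise = 0.02)
  perm <- sample(21)
  a1 <- assign_states(S, 3)
  a2 <- assign_states(structure(S[perm, perm],
                                class = class(S)), 3)
  expect_true(same_partition(a1$labels[perm], a2$labels))
  # stationary distribution and lifetimes are invariant under state
  # relabeling (compare as sorted sets)
  set.seed(16)
  s <- sample(1:3, 500, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  relab <- c(3L, 1L, 2L)
  m1 <- build_markov(s, lag = 1)
  m2 <- build_markov(relab[s], lag = 1)
  expect_equal(sort(m1$stationary), sort(m2$stationary), tolerance = 1e-12)
  expect_equal(sort(m1$lifetimes), sort(m2$lifetimes), tolerance = 1e-12)
})
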