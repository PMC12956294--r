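test_that("dominant state is the normalized-argmax and ties break low", {
  X <- rbind(c(0.1, -0.5, 0.2))
  expect_equal(dominant_states(X), 2L)

  set.seed(5)
  X <- matrix(rnorm(50 * 6), 50, 6)
  # brute-force per-row scan oracle
  oracle <- vapply(1:50, function(t) {
    r <- abs(X[t, ]) / sum(abs(X[t, ]))
    which(r == max(r))[1]
  }, integer(1))
  expect_equal(dominant_states(X), oracle)
  # normalization invariance: raw-|.| argmax equals the ratio argmax
  expect_equal(dominant_states(X), apply(abs(X), 1, which.max))

  expect_equal(dominant_states(rbind(c(2, 2, 1))), 1L) # tie to lowest index
  expect_error(dominant_states(rbind(c(0, 0, 0))),
               class = "cddfip_value_error")
})

test_that("occupancy counts and percentages conserve the window total", {
  # toy with known dominants (1,1,2,3)
  X <- rbind(c(5, 1, 0), c(4, 2, 1), c(0, 3, 1), c(1, 0, 2))
  occ <- occupancy(X)
  expect_equal(occ$count, c(2L, 1L, 1L))
  expect_equal(occ$percent, c(50, 25, 25))

  # single-state dominance
  X1 <- cbind(rep(0.1, 7), rep(0.2, 7), rep(3, 7))
  occ1 <- occupancy(X1)
  expect_equal(occ1$percent, c(0, 0, 100))

  # conservation on random input
  set.seed(9)
  Xr <- matrix(rnorm(83 * 15), 83, 15)
  occr <- occupancy(Xr)
  expect_identical(sum(occr$count), 83L)
  expect_equal(sum(occr$percent), 100, tolerance = 1e-9)
})

test_that("pairwise amplitude distances are absolute differences, symmetric, zero-diagonal", {
  X <- rbind(c(0.3, -0.1))
  d <- pairwise_amplitude_distance(X)
  expect_equal(d[1, 1, 2], 0.4)
  expect_equal(d[1, 2, 1], 0.4)
  expect_equal(d[1, 1, 1], 0)

  set.seed(3)
  Xr <- matrix(rnorm(20 * 5), 20, 5)
  dr <- pairwise_amplitude_distance(Xr)
  expect_equal(dr, aperm(dr, c(1, 3, 2)))
  expect_true(all(dr >= 0))
  for (t in c(1, 20)) expect_true(all(diag(dr[t, , ]) == 0))
  # identical columns at a window: zero distance
  Xe <- rbind(c(0.5, 0.5, 1))
  expect_equal(pairwise_amplitude_distance(Xe)[1, 1, 2], 0)
})

test_that("percentile thresholds sit at the stated quantiles and reject degeneracy", {
  set.seed(10)
  pool <- runif(200000)
  th <- select_epsilon_theta(pool)
  expect_equal(th$epsilon, 0.25, tolerance = 0.01)
  expect_equal(th$theta, 0.75, tolerance = 0.01)

  th2 <- select_epsilon_theta(rep(c(0, 1), 50))
  expect_equal(th2$epsilon, 0)
  expect_equal(th2$theta, 1)

  expect_error(select_epsilon_theta(rep(0.3, 10)),
               class = "cddfip_threshold_error")
  expect_error(select_epsilon_theta(numeric(0)),
               class = "cddfip_param_error")
})

test_that("convergence/divergence classification matches hand enumeration and stays disjoint", {
  # toy pair with d = (0.1, 0.2, 0.5, 0.9, 1.0), eps = 0.2, theta = 0.9
  d <- array(0, dim = c(5, 2, 2))
  d[, 1, 2] <- d[, 2, 1] <- c(0.1, 0.2, 0.5, 0.9, 1.0)
  cl <- classify_convergence(d, 0.2, 0.9)
  expect_equal(cl$converged_fraction[1, 2], 0.4)
  expect_equal(cl$diverged_fraction[1, 2], 0.4)

  # all-zero distances: fully converged off-diagonal
  d0 <- array(0, dim = c(4, 3, 3))
  cl0 <- classify_convergence(d0, 0.1, 0.5)
  off <- !diag(3)
  expect_true(all(cl0$converged_fraction[off] == 1))
  expect_true(all(cl0$diverged_fraction == 0))

  set.seed(2)
  Xr <- matrix(rnorm(40 * 6), 40, 6)
  dr <- pairwise_amplitude_distance(Xr)
  clr <- classify_convergence(dr, 0.3, 1.1)
  expect_true(all(clr$converged_fraction + clr$diverged_fraction <= 1 + 1e-12))
  expect_error(classify_convergence(dr, 0.9, 0.2),
               class = "cddfip_param_error")
})

test_that("state dispersion profiles are normalized histograms of the pooled distances", {
  # constant rows: all distances zero, full mass in the first bin
  Xc <- matrix(rep(c(0.2, 0.2, 0.2), each = 10), 10, 3)
  dc <- pairwise_amplitude_distance(Xc)
  expect_warning(h <- sdp_histogram(dc, seq(0.1, 1, length.out = 11)),
                 "clipped")
  expect_equal(h$density[1], 1)

  # toy multiset against hand-binned counts
  X <- rbind(c(0, 0.1, 0.6), c(0, 0.2, 1.0))
  d <- pairwise_amplitude_distance(X)
  # pairs (1,2),(1,3),(2,3) per window: 0.1,0.6,0.5, then 0.2,1.0,0.8;
  # hand-binned counts with right-closed bins: 2,1,1,2
  edges <- c(0, 0.25, 0.5, 0.75, 1)
  h2 <- sdp_histogram(d, edges)
  expect_equal(h2$density, c(2, 1, 1, 2) / 6)
  expect_equal(sum(h2$density), 1, tolerance = 1e-9)
})

test_that("state density counts strong states with a strict threshold", {
  A <- matrix(0.1, 20, 15)
  sd1 <- state_density(A, thr = 0.06)
  expect_true(all(sd1$counts == 15))
  expect_equal(sd1$pdf$probability[sd1$pdf$k == 15], 1)
  expect_equal(sum(sd1$pdf$probability), 1, tolerance = 1e-9)

  expect_true(all(state_density(matrix(0, 5, 4))$counts == 0))
  # boundary: exactly thr is not strong
  expect_equal(state_density(matrix(0.06, 3, 2), thr = 0.06)$counts,
               c(0, 0, 0))
  # negative amplitudes count through the absolute value
  expect_equal(state_density(rbind(c(-0.5, 0.01)), thr = 0.06)$counts, 1)
  expect_error(state_density(matrix(1, 2, 2), thr = 0),
               class = "cddfip_param_error")
})

test_that("group mean density averages subject distributions and stays normalized", {
  p1 <- c(1, 0, 0); p2 <- c(0, 1, 0)
  expect_equal(group_mean_density(list(p1)), p1)
  expect_equal(group_mean_density(list(p1, p2)), c(0.5, 0.5, 0))
  set.seed(4)
  pdfs <- lapply(1:7, function(i) {
    x <- runif(5); x / sum(x)
  })
  expect_equal(sum(group_mean_density(pdfs)), 1, tolerance = 1e-12)
  expect_error(group_mean_density(list(c(1, 0), c(1, 0, 0))),
               class = "cddfip_shape_error")
})

test_that("the full dynamics bundle is internally consistent on random mixings", {
  set.seed(21)
  for (rep in 1:5) {
    X <- matrix(rnorm(30 * 5, sd = runif(1, 0.5, 2)), 30, 5)
    d <- pairwise_amplitude_distance(X)
    pool <- cddfip:::pool_distances(d)
    th <- select_epsilon_theta(pool)
    dyn <- compute_dynamics(X, th$epsilon, th$theta,
                            sdp_bin_edges(pool, 20))
    expect_equal(sum(dyn$occupancy$percent), 100, tolerance = 1e-9)
    expect_equal(sum(dyn$sdp$density), 1, tolerance = 1e-9)
    expect_equal(sum(dyn$density$pdf$probability), 1, tolerance = 1e-9)
    expect_true(all(dyn$converged_fraction + dyn$diverged_fraction <= 1 + 1e-12))
    expect_equal(dyn$converged_fraction, t(dyn$converged_fraction))
  }
})
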