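test_that("scree elbow finds the knee of a planted eigenvalue spectrum", {
  # build data whose covariance eigenvalues are (10,10,10,0.1,...,0.1):
  # orthogonal directions scaled by sqrt(eigenvalue)
  set.seed(2)
  n <- 400; p <- 20
  ev <- c(10, 10, 10, rep(0.1, p - 3))
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  X <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(ev)) %*% t(Q)
  sel <- select_model_order(X, max_order = p)
  # independent chord-distance oracle over the cumulative-variance curve
  cv <- sel$curve$cumulative_variance
  ks <- seq_along(cv)
  x1 <- ks[1]; y1 <- cv[1]; x2 <- ks[length(ks)]; y2 <- cv[length(cv)]
  oracle <- abs((y2 - y1) * ks - (x2 - x1) * cv + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  expect_equal(sel$order, which.max(oracle))
  expect_equal(sel$order, 3L)
})

test_that("a linear scree has no elbow and ties break to the smallest order", {
  # exactly linear cumulative variance: whiten a centered matrix so all
  # singular values are equal (columns stay centered: span is orthogonal
  # to the ones vector)
  set.seed(3)
  X <- scale(matrix(rnorm(300 * 8), 300, 8), scale = FALSE)
  sv <- svd(X)
  Xeq <- sv$u %*% t(sv$v) * sqrt(300)
  sel <- select_model_order(Xeq, max_order = 8)
  expect_lt(max(sel$curve$chord_distance), 1e-6)
  expect_equal(sel$order, 1L)
})

test_that("planted model order is recovered on noisy synthetic concatenations", {
  hits <- vapply(1:10, function(s) {
    gt <- make_states(5, 20, seed = s)
    subs <- lapply(1:10, function(i)
      simulate_subject_dfnc(gt, W = 100, snr = 10, perturb_sd = 0,
                            seed = 100 * s + i))
    Y <- do.call(rbind, lapply(subs, function(x)
      demean_static(x$observed)$values))
    select_model_order(Y, 30)$order == 5L
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("blind ICA recovers noiseless planted states and is deterministic", {
  gt <- make_states(3, 12, seed = 11)
  subs <- lapply(1:5, function(i)
    simulate_subject_dfnc(gt, W = 80, snr = Inf, perturb_sd = 0, seed = i))
  wf <- lapply(subs, function(s) demean_static(s$observed))
  b <- fit_group_ddfips(wf, K = 3, seed = 4)
  expect_gte(min(match_abs_corr(b$states, gt$states)), 0.99)

  b2 <- fit_group_ddfips(wf, K = 3, seed = 4)
  expect_identical(b$states, b2$states)

  # sign convention: every state's max-|.| element positive; unit rows
  for (k in 1:3) {
    v <- b$states[k, ]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_equal(unname(rowSums(b$states^2)), rep(1, 3), tolerance = 1e-10)
})

test_that("dual regression is exact for basis-generated subjects and rho = 1 saturates", {
  gt <- make_states(4, 14, seed = 21)
  sub <- simulate_subject_dfnc(gt, W = 60, snr = Inf, perturb_sd = 0, seed = 3)
  wf <- demean_static(sub$observed)
  basis <- fit_group_ddfips(list(wf), K = 4, seed = 1)

  br0 <- backreconstruct_subject(wf, basis, refine_iters = 0)
  for (k in 1:4) {
    expect_gte(abs(cor(br0$subject_states[k, ], basis$states[k, ])), 1 - 1e-8)
  }

  br1 <- backreconstruct_subject(wf, basis, rho = 1, refine_iters = 10)
  for (k in 1:4) {
    expect_equal(br1$subject_states[k, ], basis$states[k, ],
                 tolerance = 1e-10)
  }
  expect_error(backreconstruct_subject(sub$observed, basis),
               class = "cddfip_state_error")
})

test_that("constrained refinement tracks subject-specific states better than the group basis", {
  co <- simulate_cohort(10, K = 5, M = 20, W = 100, snr = 5,
                        perturb_sd = 0.2, seed = 13)
  wf <- lapply(co$subjects, function(s) demean_static(s$observed))
  basis <- fit_group_ddfips(wf, K = 5, seed = 2)
  perm <- apply(abs(cor(t(basis$states), t(co$states$states))), 2, which.max)
  scores <- vapply(seq_along(wf), function(i) {
    br <- backreconstruct_subject(wf[[i]], basis, rho = 0.8,
                                  refine_iters = 10)
    St <- co$subjects[[i]]$true_states
    rec <- mean(vapply(1:5, function(k)
      abs(cor(br$subject_states[perm[k], ], St[k, ])), numeric(1)))
    bas <- mean(vapply(1:5, function(k)
      abs(cor(basis$states[perm[k], ], St[k, ])), numeric(1)))
    c(rec, bas)
  }, numeric(2))
  expect_gt(mean(scores[1, ]), mean(scores[2, ]))
  # closeness constraint honoured
  br <- backreconstruct_subject(wf[[1]], basis, rho = 0.8, refine_iters = 10)
  for (k in 1:5) {
    expect_gte(cor(br$subject_states[k, ], basis$states[k, ]), 0.8 - 1e-6)
  }
})

test_that("calibration recovers planted coefficients exactly and scales the mixing", {
  fx <- planted_calibration(K = 3, M = 10, W = 40,
                            coefs = c(0.7, -1.2, 0.4), seed = 17)
  dec <- calibrate_subject(fx$wfnc, fx$states, fx$timecourses)
  expect_equal(dec$betas, fx$coefs, tolerance = 1e-8)
  expect_equal(dec$reconstruction_r2, 1, tolerance = 1e-10)
  expect_equal(dec$calibrated_mixing,
               fx$timecourses %*% diag(fx$coefs), tolerance = 1e-8)
  # unit preservation: predictors rebuild the windowed correlations exactly
  rebuilt <- Reduce(`+`, lapply(1:3, function(k)
    dec$betas[k] * outer(dec$raw_timecourses[, k], dec$subject_states[k, ])))
  expect_equal(rebuilt, fx$wfnc, tolerance = 1e-8)
})

test_that("orthogonal calibration predictors match univariate regressions", {
  gt <- make_states(2, 8, seed = 23)
  # orthogonalize the two states and two timecourses
  S <- gt$states
  S[2, ] <- S[2, ] - sum(S[1, ] * S[2, ]) * S[1, ]
  S <- S / sqrt(rowSums(S^2))
  set.seed(8)
  A <- qr.Q(qr(matrix(rnorm(30 * 2), 30, 2))) * sqrt(29)
  A <- scale(A); attr(A, "scaled:center") <- NULL
  attr(A, "scaled:scale") <- NULL
  Y <- 0.5 * outer(A[, 1], S[1, ]) - 0.8 * outer(A[, 2], S[2, ]) +
    matrix(rnorm(30 * 28, sd = 0.01), 30, 28)
  dec <- calibrate_subject(Y, S, A)
  y <- as.numeric(Y)
  for (k in 1:2) {
    xk <- as.numeric(outer(A[, k], S[k, ]))
    expect_equal(dec$betas[k], sum(xk * y) / sum(xk^2), tolerance = 1e-6)
  }
})

test_that("pure-noise calibration explains almost nothing", {
  gt <- make_states(3, 10, seed = 29)
  set.seed(12)
  A <- scale(matrix(rnorm(60 * 3), 60, 3))
  attr(A, "scaled:center") <- NULL; attr(A, "scaled:scale") <- NULL
  Y <- matrix(rnorm(60 * 45), 60, 45)
  dec <- calibrate_subject(Y, gt$states, A)
  expect_lt(abs(dec$reconstruction_r2), 0.05)
})
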