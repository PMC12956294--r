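test_that("covariate residualization removes linear effects and is idempotent", {
  set.seed(14)
  n <- 40
  cov_df <- data.frame(age = rnorm(n, 40, 12),
                       sex = sample(c("F", "M"), n, TRUE),
                       site = sample(paste0("s", 1:3), n, TRUE))
  Y <- matrix(rnorm(n * 6), n, 6)
  R <- residualize_covariates(Y, cov_df)
  expect_lt(max(abs(cor(R, cov_df$age))), 1e-10)
  expect_lt(max(abs(colMeans(R))), 1e-12)
  # idempotent
  expect_equal(residualize_covariates(R, cov_df), R, tolerance = 1e-10)

  # exact linear relation vanishes
  Y2 <- cbind(2 * cov_df$age, -1.5 * cov_df$age + 3)
  R2 <- residualize_covariates(Y2, cov_df)
  expect_lt(max(abs(R2)), 1e-8)

  # independent covariates reduce to column demeaning
  Yd <- residualize_covariates(Y, data.frame(dummy = rep(1, n)))
  expect_equal(Yd, sweep(Y, 2, colMeans(Y)), tolerance = 1e-10)
})

test_that("cellwise t-tests match t.test feature by feature", {
  set.seed(6)
  A <- matrix(rnorm(8 * 10, mean = 0.3), 8, 10)
  B <- matrix(rnorm(12 * 10), 12, 10)
  res <- cellwise_ttest(A, B)
  for (j in c(1, 5, 10)) {
    tt <- t.test(A[, j], B[, j], var.equal = TRUE)
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[j], tt$p.value, tolerance = 1e-12)
  }
  resw <- cellwise_ttest(A, B, var_equal = FALSE)
  ttw <- t.test(A[, 3], B[, 3])
  expect_equal(resw$t[3], unname(ttw$statistic), tolerance = 1e-12)
  expect_equal(resw$p[3], ttw$p.value, tolerance = 1e-12)

  # identical samples: no difference anywhere
  resi <- cellwise_ttest(A, A)
  expect_true(all(resi$t == 0))
  expect_true(all(resi$p == 1))

  # zero-variance feature handled with a warning
  Az <- cbind(A, 1)
  Bz <- cbind(B, 1)
  expect_warning(resz <- cellwise_ttest(Az, Bz), "zero pooled variance")
  expect_equal(resz$t[11], 0)
  expect_equal(resz$p[11], 1)
})

test_that("hand-sized pooled-variance t matches the closed-form formula", {
  a <- c(1.2, 0.8, 1.5); b <- c(0.3, 0.6, 0.1)
  res <- cellwise_ttest(matrix(a), matrix(b))
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  tform <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$t[1], tform, tolerance = 1e-14)
  expect_equal(res$p[1], 2 * pt(abs(tform), 4, lower.tail = FALSE),
               tolerance = 1e-14)
})

test_that("BH correction equals the brute-force step-up oracle on random p-vectors", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.9)
  r <- bh_fdr(p, 0.05)
  expect_equal(sum(r$mask), 4)
  expect_identical(r$mask, bh_reject_oracle(p, 0.05))

  expect_equal(sum(bh_fdr(rep(1, 10), 0.05)$mask), 0)
  expect_true(bh_fdr(0.01, 0.05)$mask)
  expect_error(bh_fdr(c(0.5, 1.2)), class = "cddfip_value_error")

  set.seed(18)
  for (i in 1:300) {
    m <- sample(1:500, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    r <- bh_fdr(p, q)
    expect_identical(r$mask, bh_reject_oracle(p, q))
    expect_true(all(r$q_values >= p - 1e-15))
  }
})

test_that("signed log10 maps match elementwise evaluation", {
  expect_equal(signed_log10_map(0.01, -2), -2)
  expect_equal(signed_log10_map(1, 5), 0)
  expect_equal(signed_log10_map(0.1, 0), 0)
  set.seed(25)
  p <- matrix(runif(20, 1e-6, 1), 4, 5)
  t <- matrix(rnorm(20), 4, 5)
  expect_equal(signed_log10_map(p, t), -log10(p) * sign(t))
  # floored at 1e-300: stays finite
  expect_true(is.finite(signed_log10_map(0, 1)))
})

test_that("per-bin density tests have the right shape and directional sensitivity", {
  set.seed(33)
  mk <- function(center, n) lapply(1:n, function(i) {
    x <- dnorm(0:10, center + rnorm(1, sd = 0.4), 1.5)
    x / sum(x)
  })
  identical_groups <- per_bin_density_tests(mk(4, 10), mk(4, 10))
  expect_equal(nrow(identical_groups), 11L)

  hits <- vapply(1:40, function(r) {
    set.seed(400 + r)
    cmp <- per_bin_density_tests(mk(6, 12), mk(3, 12)) # group A shifted high
    high <- cmp$t[cmp$feature %in% paste0("k", 7:9)]
    low <- cmp$t[cmp$feature %in% paste0("k", 1:3)]
    all(high > 0) && all(low < 0) && any(cmp$significant)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  ga <- lapply(1:5, function(i) rep(0.2, 5))
  expect_warning(cmp0 <- per_bin_density_tests(ga, ga), "zero pooled variance")
  expect_true(all(cmp0$t == 0))
})

test_that("k-means on histograms separates planted families and is deterministic", {
  set.seed(3)
  H1 <- matrix(runif(20), 5, 4)
  km1 <- kmeans_histograms(H1, k = 1, seed = 2)
  expect_true(all(km1$labels == 1))
  expect_equal(as.numeric(km1$centroids), colMeans(H1), tolerance = 1e-12)

  set.seed(44)
  fam1 <- t(replicate(10, { x <- dnorm(1:8, 2, 1) + runif(8, 0, 0.02); x / sum(x) }))
  fam2 <- t(replicate(10, { x <- dnorm(1:8, 6, 1) + runif(8, 0, 0.02); x / sum(x) }))
  H <- rbind(fam1, fam2)
  km <- kmeans_histograms(H, k = 2, seed = 7, restarts = 5)
  truth <- rep(1:2, each = 10)
  agreement <- max(mean(km$labels == truth), mean(km$labels == 3 - truth))
  expect_equal(agreement, 1)

  km_b <- kmeans_histograms(H, k = 2, seed = 7, restarts = 5)
  expect_identical(km$labels, km_b$labels)
  # more restarts never worsen inertia
  km_more <- kmeans_histograms(H, k = 2, seed = 7, restarts = 20)
  expect_lte(km_more$inertia, km$inertia + 1e-12)
  expect_error(kmeans_histograms(H, k = 30, seed = 1),
               class = "cddfip_param_error")
})

test_that("null simulations keep the BH false-discovery proportion controlled", {
  set.seed(55)
  fdp <- vapply(1:100, function(r) {
    A <- matrix(rnorm(20 * 50), 20, 50)
    B <- matrix(rnorm(20 * 50), 20, 50)
    res <- cellwise_ttest(A, B)
    rej <- sum(bh_fdr(res$p, 0.05)$mask)
    rej / max(1, rej) * (rej > 0)
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})
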