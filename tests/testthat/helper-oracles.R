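# Shared test helpers: independent oracles and small fixture builders.

# greedy one-to-one matching of |correlation| between two state matrices;
# returns the matched |corr| values (used to score basis recovery)
match_abs_corr <- function(est, truth) {
  M <- abs(cor(t(est), t(truth)))
  out <- numeric(nrow(M))
  for (k in seq_len(nrow(M))) {
    ij <- which(M == max(M), arr.ind = TRUE)[1, ]
    out[k] <- M[ij[1], ij[2]]
    M[ij[1], ] <- -1
    M[, ij[2]] <- -1
  }
  out
}

# brute-force Benjamini-Hochberg step-up oracle: reject H_(i) for all
# i <= max { i : p_(i) <= i q / m }, independent of p.adjust
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thresh <- seq_len(m) * q / m
  k <- which(ps <= thresh)
  rej <- logical(m)
  if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# random symmetric matrix with zero diagonal
random_symmetric <- function(M, seed) {
  set.seed(seed)
  A <- matrix(rnorm(M * M), M, M)
  S <- A + t(A)
  diag(S) <- 0
  S
}

# per-window Pearson correlation oracle computed naively with cor()
naive_window_fnc <- function(tc, wl, step) {
  Tfull <- nrow(tc)
  W <- (Tfull - wl) %/% step + 1
  t(vapply(seq_len(W), function(w) {
    i0 <- (w - 1) * step + 1
    R <- cor(tc[i0:(i0 + wl - 1), , drop = FALSE])
    vectorize_upper(R)
  }, numeric(ncol(tc) * (ncol(tc) - 1) / 2)))
}

# planted calibration fixture: wfnc = sum_k c_k outer(a_k, s_k) with
# standardized a_k and unit-norm s_k
planted_calibration <- function(K, M, W, coefs, seed) {
  gt <- make_states(K, M, seed = seed)
  set.seed(seed + 1)
  A <- scale(matrix(rnorm(W * K), W, K))
  attr(A, "scaled:center") <- NULL
  attr(A, "scaled:scale") <- NULL
  list(states = gt$states, timecourses = A,
       wfnc = A %*% diag(coefs, K) %*% gt$states, coefs = coefs)
}
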