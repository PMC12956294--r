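# Symmetric fixed-point ICA with the log-cosh contrast.
#
# Orientation: the independent sources live over the P connectivity features
# (spatial-ICA analogue), so for a data matrix Y (W x P) each of the P
# columns is one sample of a W-dimensional observation, and the model is
# Y[, p] = A s[, p] with K independent source rows S (K x P).
#
# Whitening is done through the thin SVD of the row-centered data, the
# fixed-point iteration runs on an orthonormal K x K rotation, and
# convergence is the usual max |1 - |<w_new, w_old>|| criterion, which is
# exactly a row-angle change tolerance.

ica_gfun <- function(u) tanh(u)
ica_gprime <- function(u) 1 - tanh(u)^2

# whiten Y (W x P) across features: returns Z (K x P) with Z %*% t(Z)/P = I
ica_whiten <- function(Y, K) {
  mu <- rowMeans(Y)
  Yc <- Y - mu
  sv <- svd(Yc, nu = K, nv = K)
  if (sum(sv$d > 1e-10 * sv$d[1]) < K) {
    abort("requested order exceeds the numerical rank of the data.",
          class = "cddfip_rank_error")
  }
  P <- ncol(Y)
  Z <- t(sv$v[, seq_len(K), drop = FALSE]) * sqrt(P)
  # dewhitening map: Y ~ mu + (U D / sqrt(P)) Z
  list(Z = Z, mean = mu,
       dewhiten = sv$u[, seq_len(K), drop = FALSE] %*%
         diag(sv$d[seq_len(K)] / sqrt(P), K))
}

# symmetric orthogonalization W <- (W W^T)^{-1/2} W
sym_orth <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                     length(e$values)) %*% t(e$vectors) %*% W
}

# core symmetric FastICA on whitened data Z (K x P); returns rotation R so
# that sources S = R %*% Z.
#
# Termination: the fixed point is declared at max row-angle change < tol or
# after max_iter sweeps, whichever comes first. On noisy data the symmetric
# iteration can settle into a slow drift within a nearly
# rotation-invariant subspace; in that case the lowest-delta rotation seen
# is kept (with a warning), which is the practice of the field's FastICA
# implementations. Deterministic restarts are reserved for numerical
# breakdown (non-finite updates).
ica_fixed_point <- function(Z, seed, tol = 1e-6, max_iter = 1000L,
                            retries = 5L) {
  K <- nrow(Z); P <- ncol(Z)
  for (r in seq_len(retries)) {
    set.seed(split_seed(seed, r, 77L))
    R <- sym_orth(matrix(rnorm(K * K), K, K))
    best <- list(delta = Inf, rotation = R, iterations = 0L)
    failed <- FALSE
    for (it in seq_len(max_iter)) {
      U <- R %*% Z
      Rn <- (ica_gfun(U) %*% t(Z)) / P - diag(rowMeans(ica_gprime(U)), K) %*% R
      if (any(!is.finite(Rn))) { failed <- TRUE; break }
      Rn <- sym_orth(Rn)
      delta <- max(abs(1 - abs(rowSums(Rn * R))))
      R <- Rn
      if (delta < best$delta) {
        best <- list(delta = delta, rotation = R, iterations = it)
      }
      if (delta < tol) {
        return(list(rotation = R, iterations = it, retry = r))
      }
    }
    if (!failed) {
      warn(sprintf(
        "fixed-point ICA stopped at the %d-iteration cap (best row-angle change %.2g); keeping the most stable rotation.",
        max_iter, best$delta
      ))
      return(list(rotation = best$rotation, iterations = max_iter, retry = r))
    }
  }
  abort(sprintf("fixed-point ICA broke down numerically in %d restarts.",
                retries),
        class = "cddfip_convergence_error")
}

# apply the package's sign and scale conventions to source rows:
# unit L2 norm, maximum-magnitude element positive
fix_state_signs <- function(S) {
  S <- S / sqrt(rowSums(S^2))
  sgn <- vapply(seq_len(nrow(S)), function(k) {
    v <- S[k, ]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  sgn[sgn == 0] <- 1
  S * sgn
}
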