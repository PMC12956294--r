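#' Back-reconstruct subject-specific states against the group priors
#'
#' Two stages. Stage 1 is dual regression: the subject's raw state
#' timecourses are the least-squares projection of the demeaned windowed FNC
#' onto the group states, and the subject states are the least-squares
#' projection of the data onto those timecourses. Stage 2 (when
#' `refine_iters > 0`) refines the subject states with fixed-point
#' non-Gaussianity updates; after each update every state is pulled back
#' toward its group prior by the minimal convex blend that restores
#' `cor(subject_state_k, basis_state_k) >= rho`. States stay matched to the
#' basis by index throughout, so no permutation resolution is needed, and
#' setting `rho = 1` collapses each subject state onto its prior.
#'
#' @param wfnc Demeaned `cddfip_wfnc` for one subject.
#' @param basis `cddfip_basis` fitted on the same connectivity pairs.
#' @param rho Closeness constraint in (0, 1]: minimum correlation between a
#'   subject state and its group prior. Default 0.8.
#' @param refine_iters Number of constrained refinement iterations (0 =
#'   plain dual regression).
#' @return List with `subject_states` (`K x P`, unit-norm rows, sign-aligned
#'   to the basis) and `raw_timecourses` (`W x K`, least-squares fit of the
#'   data on the final states).
#' @export
backreconstruct_subject <- function(wfnc, basis, rho = 0.8,
                                    refine_iters = 10L) {
  stopifnot(inherits(basis, "cddfip_basis"))
  if (inherits(wfnc, "cddfip_wfnc") && !isTRUE(wfnc$demeaned)) {
    abort("windowed FNC must be demeaned before back-reconstruction.",
          class = "cddfip_state_error")
  }
  Y <- wfnc_values(wfnc)
  if (ncol(Y) != basis$n_features) {
    abort("subject data and basis have different numbers of pairs.",
          class = "cddfip_shape_error")
  }
  if (rho <= 0 || rho > 1) {
    abort("`rho` must be in (0, 1].", class = "cddfip_param_error")
  }
  B <- basis$states
  K <- nrow(B)
  # stage 1: dual regression
  TC <- t(qr.solve(tcrossprod(B), B %*% t(Y)))          # W x K
  qrTC <- qr(TC)
  rank_ok <- qrTC$rank == K
  if (!rank_ok) {
    warn("rank-deficient subject timecourses; falling back to the dual-regression result.")
    S <- qr.solve(crossprod(TC) + diag(1e-8, K), crossprod(TC, Y))
  } else {
    S <- qr.coef(qrTC, Y)                                # K x P
  }
  S <- align_to_basis(S, B)
  if (!rank_ok) {
    TC <- refit_timecourses(Y, S)
    return(list(subject_states = S, raw_timecourses = TC))
  }

  if (rho >= 1) {
    # fully saturated constraint: each state coincides with its prior
    S <- B
  } else if (refine_iters > 0L) {
    wh <- tryCatch(ica_whiten(Y, K), error = function(e) NULL)
    if (!is.null(wh)) {
      Z <- wh$Z
      P <- ncol(Y)
      for (it in seq_len(refine_iters)) {
        for (k in seq_len(K)) {
          w <- Z %*% S[k, ] / P                # whitened coordinates
          w <- w / sqrt(sum(w^2))
          u <- as.numeric(crossprod(w, Z))
          w <- Z %*% ica_gfun(u) / P - mean(ica_gprime(u)) * w
          w <- w / sqrt(sum(w^2))
          s_new <- as.numeric(crossprod(w, Z))
          S[k, ] <- enforce_closeness(s_new, B[k, ], rho)
        }
      }
      S <- align_to_basis(S, B)
    }
  }
  TC <- refit_timecourses(Y, S)
  list(subject_states = S, raw_timecourses = TC)
}

# unit-normalize rows and flip signs so cor(subject_k, basis_k) >= 0
align_to_basis <- function(S, B) {
  S <- S / pmax(sqrt(rowSums(S^2)), 1e-300)
  for (k in seq_len(nrow(S))) {
    if (cor(S[k, ], B[k, ]) < 0) S[k, ] <- -S[k, ]
  }
  S
}

refit_timecourses <- function(Y, S) {
  t(qr.solve(tcrossprod(S) + diag(1e-12, nrow(S)), S %*% t(Y)))
}

# minimal convex blend of s toward the reference b achieving cor >= rho
enforce_closeness <- function(s, b, rho) {
  s <- s / sqrt(sum(s^2))
  if (cor(s, b) < 0) s <- -s
  if (cor(s, b) >= rho) return(s)
  f <- function(alpha) {
    v <- (1 - alpha) * s + alpha * b
    cor(v, b) - rho
  }
  # cor is 1 - rho > 0 at alpha = 1 and negative at alpha = 0
  alpha <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
  v <- (1 - alpha) * s + alpha * b
  v / sqrt(sum(v^2))
}

#' Calibrate a subject's state timecourses to the original correlation scale
#'
#' Back-reconstruction returns states and timecourses only up to scale. The
#' calibration step restores units by regressing the subject's full dynamic
#' connectivity profile (the flattened demeaned windowed FNC, length `W*P`)
#' jointly onto the `K` predictors `R_k = outer(timecourse_k, state_k)`:
#' one ordinary least squares fit gives beta weights, and the calibrated
#' mixing matrix is `X = raw_timecourses %*% diag(beta)`. Because states are
#' unit-norm and timecourses are standardized before the fit, the betas
#' carry all of the scale, yielding variance-scaled timecourses on the scale
#' of the original windowed correlations.
#'
#' @param wfnc Demeaned `cddfip_wfnc` (or `W x P` matrix) for the subject.
#' @param subject_states `K x P` matrix of unit-norm subject states.
#' @param raw_timecourses `W x K` matrix; standardized internally to zero
#'   mean and unit variance per column.
#' @return A `cddfip_subject` decomposition: list with `subject_states`,
#'   `raw_timecourses` (standardized), `betas`, `calibrated_mixing`
#'   (`W x K`), `reconstruction_r2`.
#' @export
calibrate_subject <- function(wfnc, subject_states, raw_timecourses) {
  Y <- wfnc_values(wfnc)
  S <- subject_states
  K <- nrow(S)
  W <- nrow(Y)
  A <- raw_timecourses
  stopifnot(ncol(A) == K, nrow(A) == W, ncol(Y) == ncol(S))
  sds <- apply(A, 2, sd)
  if (any(sds == 0)) {
    abort("a raw timecourse is constant; cannot standardize.",
          class = "cddfip_value_error")
  }
  A <- scale(A)[, , drop = FALSE]
  attr(A, "scaled:center") <- NULL; attr(A, "scaled:scale") <- NULL
  y <- as.numeric(Y)
  # design column k is vec(outer(a_k, s_k)) = kronecker(s_k, a_k) under
  # R's column-major vec()
  D <- matrix(0, length(y), K)
  for (k in seq_len(K)) D[, k] <- as.numeric(outer(A[, k], S[k, ]))
  dsv <- svd(D)
  cond <- dsv$d[1] / max(dsv$d[K], 1e-300)
  if (!is.finite(cond) || cond > 1e10) {
    warn("collinear calibration predictors; using the minimum-norm solution.")
    pos <- dsv$d > 1e-10 * dsv$d[1]
    beta <- dsv$v[, pos, drop = FALSE] %*%
      ((t(dsv$u[, pos, drop = FALSE]) %*% y) / dsv$d[pos])
    beta <- as.numeric(beta)
  } else {
    beta <- as.numeric(qr.coef(qr(D), y))
  }
  fitted <- as.numeric(D %*% beta)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - fitted)^2) / tss else NA_real_
  structure(
    list(subject_states = S, raw_timecourses = A, betas = beta,
         calibrated_mixing = A %*% diag(beta, K),
         reconstruction_r2 = r2),
    class = "cddfip_subject"
  )
}

#' @export
print.cddfip_subject <- function(x, ...) {
  cat(sprintf(
    "<subject decomposition: %d states, %d windows, reconstruction R^2 = %.3f>\n",
    ncol(x$calibrated_mixing), nrow(x$calibrated_mixing),
    x$reconstruction_r2
  ))
  invisible(x)
}

#' Fit all subjects of a cohort against a group basis
#'
#' Convenience wrapper running [backreconstruct_subject()] and
#' [calibrate_subject()] over a list of demeaned windowed-FNC objects.
#'
#' @param wfnc_list List of demeaned `cddfip_wfnc` objects.
#' @param basis A `cddfip_basis`.
#' @inheritParams backreconstruct_subject
#' @return List of `cddfip_subject` decompositions.
#' @export
fit_subjects <- function(wfnc_list, basis, rho = 0.8, refine_iters = 10L) {
  lapply(wfnc_list, function(w) {
    br <- backreconstruct_subject(w, basis, rho = rho,
                                  refine_iters = refine_iters)
    calibrate_subject(w, br$subject_states, br$raw_timecourses)
  })
}
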