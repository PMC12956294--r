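#' Fit group-level dynamic connectivity states (ddFIPs) by blind ICA
#'
#' Concatenates all subjects' demeaned windowed-FNC rows, whitens to `K`
#' principal dimensions, and runs symmetric fixed-point ICA with the
#' log-cosh non-Gaussianity contrast over the connectivity features. The
#' resulting independent source rows are the group states ("ddFIPs"):
#' overlapping connectivity templates that every subject's dynamic
#' connectivity is later expressed in. Each state is re-normalized to unit
#' L2 with its maximum-magnitude element made positive, so the basis has a
#' fixed sign and scale convention. The whole fit is deterministic given
#' `(input, K, seed)`; non-convergence triggers up to 5 deterministic
#' restarts before erroring.
#'
#' @param concat `W_total x P` stacked matrix, a list of `cddfip_wfnc`
#'   objects, or a single `cddfip_wfnc`.
#' @param K Number of states to extract (e.g. 15 at full imaging scale; use
#'   [select_model_order()] to choose objectively).
#' @param seed Integer seed for the ICA initialization.
#' @param tol Convergence tolerance on the maximum row-angle change.
#' @param max_iter Maximum fixed-point iterations per restart.
#' @return A `cddfip_basis`: list with `states` (`K x P`, unit-norm rows),
#'   `explained_variance` (variance share of each whitened dimension),
#'   `order_selection_curve` (scree tibble from [select_model_order()] when
#'   computable), `K`, `seed`, `ica_iterations`.
#' @export
#' @examples
#' gt <- make_states(3, 10, seed = 2)
#' subs <- lapply(1:4, function(i)
#'   simulate_subject_dfnc(gt, W = 60, snr = 20, perturb_sd = 0, seed = i))
#' wf <- lapply(subs, function(s) demean_static(s$observed))
#' basis <- fit_group_ddfips(wf, K = 3, seed = 1)
fit_group_ddfips <- function(concat, K, seed = 1L, tol = 1e-6,
                             max_iter = 1000L) {
  Y <- stack_wfnc(concat)
  K <- as.integer(K)
  if (K < 1L) abort("`K` must be >= 1.", class = "cddfip_param_error")
  wh <- ica_whiten(Y, K) # sources live over the P connectivity features
  fit <- ica_fixed_point(wh$Z, seed = seed, tol = tol, max_iter = max_iter)
  S <- fit$rotation %*% wh$Z
  S <- fix_state_signs(S)
  d2 <- svd(sweep(Y, 2, colMeans(Y), "-"), nu = 0, nv = 0)$d^2
  explained <- (d2 / sum(d2))[seq_len(K)]
  structure(
    list(states = S, explained_variance = explained, K = K,
         seed = as.integer(seed), ica_iterations = fit$iterations,
         n_features = ncol(Y)),
    class = "cddfip_basis"
  )
}

#' @export
print.cddfip_basis <- function(x, ...) {
  cat(sprintf(
    "<ddFIP basis: %d states x %d connectivity pairs (seed %d, %d ICA iterations)>\n",
    x$K, x$n_features, x$seed, x$ica_iterations
  ))
  invisible(x)
}
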