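#' Tidy a ddFIP basis into a long tibble
#'
#' @param x A `cddfip_basis`.
#' @param ... Unused.
#' @return Tibble with columns `state`, `pair`, `loading`.
#' @method tidy cddfip_basis
#' @export
tidy.cddfip_basis <- function(x, ...) {
  tibble::tibble(
    state = rep(seq_len(x$K), each = x$n_features),
    pair = rep(seq_len(x$n_features), times = x$K),
    loading = as.numeric(t(x$states))
  )
}

#' One-row summary of a ddFIP basis
#' @inheritParams tidy.cddfip_basis
#' @return Tibble with `k`, `n_pairs`, `explained_variance`,
#'   `ica_iterations`, `seed`.
#' @method glance cddfip_basis
#' @export
glance.cddfip_basis <- function(x, ...) {
  tibble::tibble(
    k = x$K, n_pairs = x$n_features,
    explained_variance = sum(x$explained_variance),
    ica_iterations = x$ica_iterations, seed = x$seed
  )
}

#' Tidy a subject decomposition: calibrated amplitudes in long form
#'
#' @param x A `cddfip_subject`.
#' @param ... Unused.
#' @return Tibble with `window`, `state`, `amplitude`, `beta`.
#' @method tidy cddfip_subject
#' @export
tidy.cddfip_subject <- function(x, ...) {
  X <- x$calibrated_mixing
  tibble::tibble(
    window = rep(seq_len(nrow(X)), times = ncol(X)),
    state = rep(seq_len(ncol(X)), each = nrow(X)),
    amplitude = as.numeric(X),
    beta = rep(x$betas, each = nrow(X))
  )
}

#' One-row summary of a subject decomposition
#' @inheritParams tidy.cddfip_subject
#' @return Tibble with `n_windows`, `n_states`, `reconstruction_r2`,
#'   `min_beta`, `max_beta`.
#' @method glance cddfip_subject
#' @export
glance.cddfip_subject <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$calibrated_mixing),
    n_states = ncol(x$calibrated_mixing),
    reconstruction_r2 = x$reconstruction_r2,
    min_beta = min(x$betas), max_beta = max(x$betas)
  )
}

#' Tidy a group comparison (already tabular; returns the tibble)
#' @param x A `cddfip_comparison`.
#' @param ... Unused.
#' @method tidy cddfip_comparison
#' @export
tidy.cddfip_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a group comparison
#' @inheritParams tidy.cddfip_comparison
#' @return Tibble with `n_features`, `n_significant`, `q_threshold`,
#'   `min_q`.
#' @method glance cddfip_comparison
#' @export
glance.cddfip_comparison <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x), n_significant = sum(x$significant),
    q_threshold = attr(x, "q_threshold"), min_q = min(x$q)
  )
}

#' Tidy a histogram clustering
#' @param x A `cddfip_kmeans`.
#' @param ... Unused.
#' @return Tibble with `subject`, `cluster`.
#' @method tidy cddfip_kmeans
#' @export
tidy.cddfip_kmeans <- function(x, ...) {
  tibble::tibble(subject = seq_along(x$labels), cluster = x$labels)
}

#' One-row summary of a histogram clustering
#' @inheritParams tidy.cddfip_kmeans
#' @method glance cddfip_kmeans
#' @export
glance.cddfip_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia, restarts = x$restarts,
                 seed = x$seed)
}
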