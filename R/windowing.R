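#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Connectivity matrices are symmetric with an uninformative diagonal, so the
#' pipeline works on the strict upper triangle flattened in row-major order:
#' for an `M x M` matrix this gives a vector of length `P = M(M-1)/2`
#' (e.g. 1378 pairs for the 53-network parcellation commonly used in dFNC
#' work).
#'
#' @param C A symmetric numeric matrix (asymmetry beyond `tol` is an error).
#' @param tol Symmetry tolerance, default `1e-8`.
#' @return Numeric vector of length `M(M-1)/2`, ordered `(1,2), (1,3), ...,
#'   (1,M), (2,3), ...` so that [devectorize_upper()] inverts it exactly.
#' @seealso [devectorize_upper()]
#' @export
#' @examples
#' C <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' vectorize_upper(C)
vectorize_upper <- function(C, tol = 1e-8) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) {
    abort("`C` must be a square matrix.", class = "cddfip_shape_error")
  }
  if (max(abs(C - t(C))) > tol) {
    abort(
      sprintf("`C` is asymmetric beyond tolerance %g.", tol),
      class = "cddfip_shape_error"
    )
  }
  # row-major strict upper triangle == column-major lower triangle of t(C)
  tC <- t(C)
  tC[lower.tri(tC)]
}

#' Rebuild a symmetric matrix from its vectorized upper triangle
#'
#' @param v Numeric vector of length `M(M-1)/2` for some integer `M`.
#' @return `M x M` symmetric matrix with zero diagonal.
#' @export
devectorize_upper <- function(v) {
  P <- length(v)
  M <- (1 + sqrt(1 + 8 * P)) / 2
  if (abs(M - round(M)) > 1e-9) {
    abort("length(v) is not M(M-1)/2 for any integer M.",
          class = "cddfip_shape_error")
  }
  M <- as.integer(round(M))
  C <- matrix(0, M, M)
  tC <- t(C)
  tC[lower.tri(tC)] <- v
  C <- t(tC)
  C + t(C)
}

#' Number of connectivity pairs for M networks
#' @param M Number of networks.
#' @return `M(M-1)/2`.
#' @export
n_pairs <- function(M) as.integer(M * (M - 1) / 2)

#' Convert a window length in seconds to TRs
#'
#' The window is specified in seconds in the literature (45 s is typical for
#' sliding-window FNC); sampling is in units of the repetition time (TR).
#' Conversion rounds to the nearest TR with exact halves rounded down, so a
#' 45 s window at TR = 2 s becomes 22 TRs.
#'
#' @param seconds Window length in seconds.
#' @param tr_seconds Repetition time in seconds.
#' @return Integer window length in TRs.
#' @export
window_len_from_seconds <- function(seconds, tr_seconds) {
  stopifnot(seconds > 0, tr_seconds > 0)
  x <- seconds / tr_seconds
  as.integer(ceiling(x - 0.5))
}

#' Sliding-window functional network connectivity
#'
#' Slides a rectangular window of `window_len_tr` samples along the
#' timecourses in steps of `step_tr` TRs and computes the Pearson correlation
#' matrix of each window, vectorized via [vectorize_upper()]. No Fisher
#' transform and no taper are applied. Window `w` (0-based) covers rows
#' `[w*step, w*step + window_len_tr)`, giving
#' `W = floor((T - window_len_tr)/step_tr) + 1` windows.
#'
#' A column that is constant within a window has undefined correlations; the
#' affected pairs are set to 0 with a warning rather than propagating `NaN`,
#' which keeps the downstream decomposition well-posed.
#'
#' @param tc `T x M` numeric matrix of network timecourses (or an object from
#'   [read_timecourses()]).
#' @param window_len_tr Window length in TRs (>= 3).
#' @param step_tr Step between window starts in TRs, default 1.
#' @return A `cddfip_wfnc` object: list with `values` (`W x P` matrix),
#'   `window_len_tr`, `step_tr`, `demeaned = FALSE`, `n_networks`.
#' @export
sliding_window_fnc <- function(tc, window_len_tr, step_tr = 1L) {
  if (inherits(tc, "cddfip_timecourses")) tc <- tc$values
  stopifnot(is.matrix(tc), is.numeric(tc))
  if (any(!is.finite(tc))) {
    abort("timecourses contain non-finite values.", class = "cddfip_value_error")
  }
  window_len_tr <- as.integer(window_len_tr)
  step_tr <- as.integer(step_tr)
  Tfull <- nrow(tc)
  M <- ncol(tc)
  if (window_len_tr < 3L) {
    abort("`window_len_tr` must be at least 3.", class = "cddfip_param_error")
  }
  if (Tfull < window_len_tr) {
    abort("timecourses shorter than one window.", class = "cddfip_param_error")
  }
  W <- (Tfull - window_len_tr) %/% step_tr + 1L
  P <- n_pairs(M)
  values <- matrix(0, W, P)
  n_const <- 0L
  for (w in seq_len(W)) {
    i0 <- (w - 1L) * step_tr + 1L
    seg <- tc[i0:(i0 + window_len_tr - 1L), , drop = FALSE]
    sds <- apply(seg, 2, sd)
    if (any(sds == 0)) {
      n_const <- n_const + 1L
      R <- suppressWarnings(cor(seg))
      R[!is.finite(R)] <- 0
    } else {
      R <- cor(seg)
    }
    values[w, ] <- vectorize_upper(R, tol = 1e-6)
  }
  if (n_const > 0L) {
    warn(sprintf(
      "%d window(s) contained a constant column; affected correlations set to 0.",
      n_const
    ))
  }
  structure(
    list(
      values = values, window_len_tr = window_len_tr, step_tr = step_tr,
      demeaned = FALSE, static_fnc = NULL, n_networks = M
    ),
    class = "cddfip_wfnc"
  )
}

#' Remove the static connectivity term from windowed FNC
#'
#' Each connectivity pair's mean across windows is that subject's static FNC;
#' subtracting it isolates the dynamic fluctuation around the baseline. The
#' removed means are stored in `static_fnc` so the raw windows can always be
#' reconstructed exactly as `values + static_fnc`.
#'
#' @param wfnc A `cddfip_wfnc` object that has not been demeaned yet.
#' @return The demeaned `cddfip_wfnc` with `static_fnc` filled in.
#' @export
demean_static <- function(wfnc) {
  stopifnot(inherits(wfnc, "cddfip_wfnc"))
  if (isTRUE(wfnc$demeaned)) {
    abort("windowed FNC is already demeaned.", class = "cddfip_state_error")
  }
  mu <- colMeans(wfnc$values)
  wfnc$values <- sweep(wfnc$values, 2, mu, "-")
  wfnc$static_fnc <- mu
  wfnc$demeaned <- TRUE
  wfnc
}

#' @export
print.cddfip_wfnc <- function(x, ...) {
  cat(sprintf(
    "<windowed FNC: %d windows x %d pairs (%d networks), window %d TR, step %d TR, %s>\n",
    nrow(x$values), ncol(x$values), x$n_networks, x$window_len_tr, x$step_tr,
    if (isTRUE(x$demeaned)) "demeaned" else "raw"
  ))
  invisible(x)
}

# internal: accept a bare matrix or a wfnc, return W x P matrix
wfnc_values <- function(x) {
  if (inherits(x, "cddfip_wfnc")) x$values else x
}

#' Wrap a precomputed windowed-FNC matrix
#'
#' For pipelines that start from already-windowed connectivity (e.g. files
#' produced by another toolbox): wraps a `W x P` matrix as a windowed-FNC
#' object, inferring the network count from `P = M(M-1)/2`.
#'
#' @param values `W x P` numeric matrix of vectorized windowed correlations.
#' @param window_len_tr,step_tr Optional provenance (window parameters used
#'   upstream).
#' @return A raw (not demeaned) `cddfip_wfnc` object.
#' @export
as_wfnc <- function(values, window_len_tr = NA_integer_, step_tr = 1L) {
  stopifnot(is.matrix(values), is.numeric(values))
  M <- (1 + sqrt(1 + 8 * ncol(values))) / 2
  if (abs(M - round(M)) > 1e-9) {
    abort("ncol(values) is not M(M-1)/2 for any integer M.",
          class = "cddfip_shape_error")
  }
  structure(
    list(values = values, window_len_tr = as.integer(window_len_tr),
         step_tr = as.integer(step_tr), demeaned = FALSE, static_fnc = NULL,
         n_networks = as.integer(round(M))),
    class = "cddfip_wfnc"
  )
}
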