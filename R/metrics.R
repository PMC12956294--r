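#' Dominant state per window
#'
#' At each window the dominant state is the one with maximum relative
#' activity `|x_i(t)| / sum_j |x_j(t)|`; since the denominator is common and
#' positive, this is the argmax of the absolute calibrated amplitudes. Ties
#' break to the lowest state index.
#'
#' @param X `T x N` calibrated mixing matrix (or `cddfip_subject`, whose
#'   `calibrated_mixing` is used).
#' @return Integer vector of length `T` with state indices in `1..N`.
#' @export
dominant_states <- function(X) {
  X <- mixing_values(X)
  aX <- abs(X)
  if (any(rowSums(aX) == 0)) {
    abort("a window has all-zero amplitudes: dominance undefined.",
          class = "cddfip_value_error")
  }
  apply(aX, 1, which.max)
}

#' State occupancy counts and percentages
#'
#' The occupancy count of state `i` is the number of windows where it is
#' dominant; the percentage is the count over the total number of windows,
#' times 100, so the percentages always sum to exactly 100.
#'
#' @inheritParams dominant_states
#' @return A `cddfip_occupancy` tibble with one row per state: `state`,
#'   `count`, `percent`; attributes `dominant` (the per-window dominant
#'   state vector) and `n_windows`.
#' @export
occupancy <- function(X) {
  X <- mixing_values(X)
  Tn <- nrow(X); N <- ncol(X)
  dom <- dominant_states(X)
  counts <- tabulate(dom, nbins = N)
  out <- tibble::tibble(
    state = seq_len(N), count = counts, percent = counts / Tn * 100
  )
  attr(out, "dominant") <- dom
  attr(out, "n_windows") <- Tn
  class(out) <- c("cddfip_occupancy", class(out))
  out
}

#' Pairwise amplitude distances between states
#'
#' The distance between states `i` and `j` at window `t` is the Euclidean
#' norm of the difference between their scalar calibrated amplitudes, i.e.
#' `|x_i(t) - x_j(t)|`. Small distances mean the two states contribute
#' similarly at that moment (convergence); large distances mean uneven
#' contributions (divergence).
#'
#' @inheritParams dominant_states
#' @return `T x N x N` array, symmetric in its last two margins with zero
#'   diagonal.
#' @export
pairwise_amplitude_distance <- function(X) {
  X <- mixing_values(X)
  Tn <- nrow(X); N <- ncol(X)
  d <- array(0, dim = c(Tn, N, N))
  for (i in seq_len(N)) for (j in seq_len(N)) {
    d[, i, j] <- abs(X[, i] - X[, j])
  }
  d
}

# upper-triangle (i < j) distances of a T x N x N tensor, as one vector
pool_distances <- function(d) {
  N <- dim(d)[2]
  idx <- which(upper.tri(matrix(0, N, N)))
  as.numeric(apply(d, 1, function(m) m[idx]))
}

#' Select convergence/divergence thresholds from pooled distances
#'
#' The thresholds epsilon (converged) and theta (diverged) are data-driven:
#' by default the 25th and 75th percentiles of the pairwise distances pooled
#' across subjects, windows and state pairs, which puts the unclassified
#' band over the middle half of the empirical distance distribution.
#'
#' @param pool Numeric vector of pooled distances (e.g. concatenated
#'   [pool_distances()] output across subjects).
#' @param method Only `"percentile"` is implemented.
#' @param probs Length-2 probabilities for (epsilon, theta).
#' @return Named list `list(epsilon, theta)` with `epsilon < theta`.
#' @export
select_epsilon_theta <- function(pool, method = "percentile",
                                 probs = c(0.25, 0.75)) {
  if (length(pool) == 0) {
    abort("empty distance pool.", class = "cddfip_param_error")
  }
  method <- match.arg(method)
  q <- unname(quantile(pool, probs = probs, type = 7))
  if (!(q[1] < q[2])) {
    abort("degenerate distance pool: epsilon would equal theta.",
          class = "cddfip_threshold_error")
  }
  list(epsilon = q[1], theta = q[2])
}

#' Classify windows as converged or diverged per state pair
#'
#' A window is converged for pair `(i, j)` when `d_ij(t) <= epsilon` and
#' diverged when `d_ij(t) >= theta`; distances strictly between the
#' thresholds stay unclassified, so the two per-pair fractions always sum to
#' at most 1. The diagonal is excluded (set to 0).
#'
#' @param d `T x N x N` distance array from
#'   [pairwise_amplitude_distance()].
#' @param epsilon,theta Thresholds with `epsilon < theta`.
#' @return List with `converged_fraction` and `diverged_fraction` (`N x N`
#'   symmetric matrices, zero diagonal).
#' @export
classify_convergence <- function(d, epsilon, theta) {
  if (epsilon >= theta) {
    abort("`epsilon` must be strictly less than `theta`.",
          class = "cddfip_param_error")
  }
  Tn <- dim(d)[1]; N <- dim(d)[2]
  conv <- apply(d <= epsilon, c(2, 3), mean)
  divg <- apply(d >= theta, c(2, 3), mean)
  diag(conv) <- 0
  diag(divg) <- 0
  list(converged_fraction = conv, diverged_fraction = divg)
}

#' State dispersion profile (SDP)
#'
#' The SDP is a subject's normalized histogram of all pairwise amplitude
#' distances (pairs `i < j`, all windows): a threshold-free picture of how
#' converged or dispersed the state amplitudes are. Bin edges are shared
#' across subjects so group curves are comparable; values outside the
#' outermost edges are clipped into the end bins with a warning.
#'
#' @param d `T x N x N` distance array for one subject.
#' @param bin_edges Increasing numeric vector of shared bin edges.
#' @return A `cddfip_sdp` tibble: `bin`, `lower`, `upper`, `density`
#'   (per-bin probability summing to 1).
#' @export
sdp_histogram <- function(d, bin_edges) {
  vals <- pool_distances(d)
  if (length(vals) == 0) {
    abort("no pairwise distances to bin.", class = "cddfip_param_error")
  }
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges))
  lo <- bin_edges[1]; hi <- bin_edges[length(bin_edges)]
  if (any(vals < lo) || any(vals > hi)) {
    warn("distances outside the shared bin range; clipped into end bins.")
    vals <- pmin(pmax(vals, lo), hi)
  }
  cuts <- cut(vals, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
  counts <- as.numeric(table(cuts))
  nb <- length(bin_edges) - 1L
  out <- tibble::tibble(
    bin = seq_len(nb),
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1],
    density = counts / sum(counts)
  )
  class(out) <- c("cddfip_sdp", class(out))
  out
}

#' Shared SDP bin edges for a cohort
#'
#' @param pool Pooled distances across the cohort.
#' @param n_bins Number of equal-width bins (default 50).
#' @return Numeric vector of `n_bins + 1` edges spanning `range(pool)`.
#' @export
sdp_bin_edges <- function(pool, n_bins = 50L) {
  r <- range(pool)
  if (r[1] == r[2]) r[2] <- r[1] + 1e-12
  seq(r[1], r[2], length.out = n_bins + 1L)
}

#' Dynamic state density
#'
#' A state is "strong" at a window when its absolute calibrated amplitude
#' strictly exceeds `thr` (default 0.06). The state density `S_t` counts the
#' strong states per window; its histogram over `0..N_c`, normalized by the
#' number of windows, is the subject's state-density probability
#' distribution.
#'
#' @param A `T x N_c` amplitude matrix (calibrated mixing).
#' @param thr Strong-state threshold (> 0), default 0.06.
#' @return A `cddfip_density` list: `indicator` (`T x N_c` binary), `counts`
#'   (`S_t`, length `T`), `pdf` (tibble `k`, `probability` over
#'   `k = 0..N_c`), `thr`.
#' @export
state_density <- function(A, thr = 0.06) {
  A <- mixing_values(A)
  if (thr <= 0) abort("`thr` must be positive.", class = "cddfip_param_error")
  Nc <- ncol(A); Tn <- nrow(A)
  I <- (abs(A) > thr) * 1L
  S_t <- rowSums(I)
  pdf <- vapply(0:Nc, function(k) sum(S_t == k) / Tn, numeric(1))
  structure(
    list(indicator = I, counts = S_t,
         pdf = tibble::tibble(k = 0:Nc, probability = pdf), thr = thr,
         n_states = Nc, n_windows = Tn),
    class = "cddfip_density"
  )
}

#' Group-average state-density distribution
#'
#' Elementwise mean of the subjects' normalized state-density histograms;
#' the mean of distributions is again a distribution.
#'
#' @param pdfs List of per-subject pdf vectors (or `cddfip_density`
#'   objects), all of the same length.
#' @return Numeric vector of mean probabilities over `k = 0..N_c`.
#' @export
group_mean_density <- function(pdfs) {
  vecs <- lapply(pdfs, function(p) {
    if (inherits(p, "cddfip_density")) p$pdf$probability else as.numeric(p)
  })
  len <- unique(lengths(vecs))
  if (length(len) != 1) {
    abort("subject pdfs have mismatched lengths.", class = "cddfip_shape_error")
  }
  Reduce(`+`, vecs) / length(vecs)
}

#' Compute the full dynamics bundle for one subject
#'
#' @param X Calibrated mixing matrix or `cddfip_subject`.
#' @param epsilon,theta Convergence/divergence thresholds (cohort-level; see
#'   [select_epsilon_theta()]).
#' @param bin_edges Shared SDP bin edges (see [sdp_bin_edges()]).
#' @param thr Strong-state threshold for the density.
#' @return A `cddfip_dynamics` list: `occupancy`, `converged_fraction`,
#'   `diverged_fraction`, `sdp`, `density`.
#' @export
compute_dynamics <- function(X, epsilon, theta, bin_edges, thr = 0.06) {
  X <- mixing_values(X)
  d <- pairwise_amplitude_distance(X)
  cls <- classify_convergence(d, epsilon, theta)
  structure(
    list(
      occupancy = occupancy(X),
      converged_fraction = cls$converged_fraction,
      diverged_fraction = cls$diverged_fraction,
      sdp = sdp_histogram(d, bin_edges),
      density = state_density(X, thr = thr)
    ),
    class = "cddfip_dynamics"
  )
}

mixing_values <- function(X) {
  if (inherits(X, "cddfip_subject")) X <- X$calibrated_mixing
  stopifnot(is.matrix(X), is.numeric(X))
  if (any(!is.finite(X))) {
    abort("mixing matrix contains non-finite values.",
          class = "cddfip_value_error")
  }
  X
}
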