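#' Residualize metric features on covariates
#'
#' Regresses each feature column on an intercept plus the covariates
#' (categorical columns one-hot encoded with the first level dropped) and
#' returns the residuals, which are orthogonal to every design column. The
#' operation is idempotent. Collinear design columns are dropped with a
#' warning.
#'
#' @param Y `subjects x features` numeric matrix (or data frame of
#'   numerics).
#' @param covariates Data frame with one row per subject; numeric columns
#'   enter as-is, character/factor columns are one-hot encoded.
#' @return Residual matrix with the same shape and dimnames as `Y`.
#' @export
residualize_covariates <- function(Y, covariates) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(covariates))
  C <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    warn(sprintf("dropping %d collinear covariate column(s).",
                 ncol(C) - qrC$rank))
    C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
    qrC <- qr(C)
  }
  res <- qr.resid(qrC, Y)
  dimnames(res) <- dimnames(Y)
  res
}

#' Cellwise two-sample t-tests
#'
#' Independent pooled-variance (Student) two-sample t-test applied to every
#' feature column at once, with two-sided p-values. Welch's unequal-variance
#' form is available via `var_equal = FALSE`. Features with zero pooled
#' variance get `t = 0, p = 1` with a warning.
#'
#' @param A,B `subjects x features` matrices for the two groups (>= 2
#'   subjects each).
#' @param var_equal Pooled-variance Student test when `TRUE` (default),
#'   Welch otherwise.
#' @return List with numeric vectors `t` and `p` (length = features) and
#'   `df`.
#' @export
cellwise_ttest <- function(A, B, var_equal = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B))
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2 || n2 < 2) {
    abort("need at least 2 subjects per group.", class = "cddfip_param_error")
  }
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, var); v2 <- apply(B, 2, var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  zero <- !is.finite(tval)
  if (any(zero)) {
    warn(sprintf("%d feature(s) with zero pooled variance; t = 0, p = 1.",
                 sum(zero)))
    tval[zero] <- 0
    df[zero] <- n1 + n2 - 2
  }
  p <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  list(t = tval, p = p, df = df)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a flat vector of p-values; the returned q-values
#' are the monotone BH-adjusted p-values and the mask flags
#' `q <= q_threshold` (the inclusive boundary of the step-up rule).
#' For a symmetric comparison matrix, pass the unique upper-triangle cells
#' so each matrix forms one correction family.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q_threshold FDR level, default 0.05.
#' @return List with `q_values` and logical `mask`.
#' @export
bh_fdr <- function(p, q_threshold = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].", class = "cddfip_value_error")
  }
  q <- p.adjust(p, method = "BH")
  # step-up boundary is inclusive: reject when p_(i) <= i q / m, i.e. q <= level
  list(q_values = q, mask = q <= q_threshold)
}

#' Signed log10 significance map
#'
#' `-log10(p) * sign(t)`: magnitude encodes significance, sign encodes the
#' direction of the group difference. p-values are floored at `1e-300` so
#' the map stays finite.
#'
#' @param p,t Same-shape numeric arrays.
#' @return Array of the same shape.
#' @export
signed_log10_map <- function(p, t) {
  stopifnot(length(p) == length(t))
  out <- -log10(pmax(p, 1e-300)) * sign(t)
  if (is.matrix(p)) out <- matrix(out, nrow(p), ncol(p), dimnames = dimnames(p))
  out
}

#' Compare two groups cellwise with FDR control
#'
#' Runs [cellwise_ttest()] feature-by-feature, applies [bh_fdr()] across the
#' family of features, and attaches the signed-log significance map. This is
#' the engine behind both connectivity-pair comparisons (converged/diverged
#' fraction matrices, unique upper-triangle cells as one family) and per-bin
#' density comparisons.
#'
#' @inheritParams cellwise_ttest
#' @param q_threshold FDR level.
#' @param feature_names Optional feature labels.
#' @return A `cddfip_comparison` tibble: `feature`, `mean_a`, `mean_b`,
#'   `t`, `p`, `q`, `signed_log10`, `significant`.
#' @export
compare_groups <- function(A, B, q_threshold = 0.05, var_equal = TRUE,
                           feature_names = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  tt <- cellwise_ttest(A, B, var_equal = var_equal)
  fdr <- bh_fdr(tt$p, q_threshold = q_threshold)
  if (is.null(feature_names)) {
    feature_names <- colnames(A) %||% paste0("f", seq_len(ncol(A)))
  }
  out <- tibble::tibble(
    feature = feature_names,
    mean_a = colMeans(A), mean_b = colMeans(B),
    t = tt$t, p = tt$p, q = fdr$q_values,
    signed_log10 = signed_log10_map(tt$p, tt$t),
    significant = fdr$mask
  )
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("cddfip_comparison", class(out))
  out
}

#' Per-bin state-density group comparison
#'
#' Two-sample t-tests on each state-density histogram bin (`k = 0..N_c`)
#' between two groups of subjects, with BH-FDR across bins and the
#' signed-log map attached.
#'
#' @param pdfs_a,pdfs_b Lists of per-subject pdf vectors (or
#'   `cddfip_density` objects) for the two groups.
#' @inheritParams compare_groups
#' @return A `cddfip_comparison` tibble with one row per bin.
#' @export
per_bin_density_tests <- function(pdfs_a, pdfs_b, q_threshold = 0.05,
                                  var_equal = TRUE) {
  to_mat <- function(pdfs) {
    do.call(rbind, lapply(pdfs, function(p) {
      if (inherits(p, "cddfip_density")) p$pdf$probability else as.numeric(p)
    }))
  }
  Ma <- to_mat(pdfs_a); Mb <- to_mat(pdfs_b)
  if (ncol(Ma) != ncol(Mb)) {
    abort("groups have different bin counts.", class = "cddfip_shape_error")
  }
  compare_groups(Ma, Mb, q_threshold = q_threshold, var_equal = var_equal,
                 feature_names = paste0("k", seq_len(ncol(Ma)) - 1L))
}

#' Cluster state-density histograms with k-means
#'
#' Euclidean k-means on the subjects' normalized histograms (best of
#' `restarts` runs by within-cluster sum of squares), used to group similar
#' density profiles across subjects. Deterministic given `(H, k, seed,
#' restarts)`.
#'
#' @param H `subjects x bins` matrix of normalized histograms.
#' @param k Number of clusters (default 3).
#' @param seed Integer seed.
#' @param restarts Number of random restarts (best by inertia).
#' @return A `cddfip_kmeans` list: `labels`, `centroids`, `inertia`, `k`,
#'   `seed`, `restarts`.
#' @export
kmeans_histograms <- function(H, k = 3L, seed = 1L, restarts = 10L) {
  H <- as.matrix(H)
  k <- as.integer(k)
  if (k > nrow(H)) {
    abort("`k` exceeds the number of subjects.", class = "cddfip_param_error")
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  km <- tryCatch(
    kmeans(H, centers = k, nstart = as.integer(restarts), iter.max = 100L),
    error = function(e) {
      # rare empty-cluster failure in Hartigan-Wong: fall back to Lloyd
      set.seed(as.integer(seed) %% .Machine$integer.max)
      kmeans(H, centers = k, nstart = as.integer(restarts), iter.max = 100L,
             algorithm = "Lloyd")
    }
  )
  structure(
    list(labels = km$cluster, centroids = km$centers,
         inertia = km$tot.withinss, k = k, seed = as.integer(seed),
         restarts = as.integer(restarts)),
    class = "cddfip_kmeans"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
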