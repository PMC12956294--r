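#' Select the number of states by the scree-elbow criterion
#'
#' Runs PCA on the concatenated (column-centered) windowed-FNC matrix and
#' picks the elbow of the cumulative explained-variance scree: the component
#' count `k` whose scree point is farthest (perpendicular distance) from the
#' chord joining the first and last points of the curve. Ties break to the
#' smallest `k`, and a curve with no curvature therefore returns 1.
#'
#' @param concat `W_total x P` matrix of stacked windowed-FNC rows (all
#'   subjects), or a list of `cddfip_wfnc` objects which will be stacked.
#' @param max_order Largest order to consider (<= `min(W_total, P)`).
#' @return A list with `order` (the selected count), `curve` (tibble:
#'   component, eigenvalue, cumulative_variance, chord_distance) for scree
#'   plotting.
#' @export
select_model_order <- function(concat, max_order = 30L) {
  concat <- stack_wfnc(concat)
  max_order <- as.integer(max_order)
  if (max_order > min(dim(concat))) {
    abort("`max_order` exceeds min(W_total, P).", class = "cddfip_param_error")
  }
  Xc <- sweep(concat, 2, colMeans(concat), "-")
  d <- svd(Xc, nu = 0, nv = 0)$d
  ev <- d^2 / max(1, nrow(concat) - 1)
  ev <- ev[seq_len(max_order)]
  if (sum(ev[-1]) <= 1e-12 * ev[1]) {
    warn("input is effectively rank 1; returning order 1.")
    curve <- tibble::tibble(component = seq_len(max_order), eigenvalue = ev,
                            cumulative_variance = cumsum(ev) / sum(ev),
                            chord_distance = 0)
    return(list(order = 1L, curve = curve))
  }
  cv <- cumsum(ev) / sum(ev)
  dist <- chord_distance(seq_len(max_order), cv)
  # smallest k within numerical tie of the maximum distance, so a flat
  # (curvature-free) scree resolves to order 1
  k <- which(dist >= max(dist) - 1e-9)[1]
  list(
    order = as.integer(k),
    curve = tibble::tibble(component = seq_len(max_order), eigenvalue = ev,
                           cumulative_variance = cv, chord_distance = dist)
  )
}

# perpendicular distance of each point (x, y) from the chord joining the
# first and last point of the curve
chord_distance <- function(x, y) {
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len == 0) return(rep(0, length(x)))
  abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) / len
}

# stack per-subject windowed FNC into one W_total x P matrix
stack_wfnc <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "cddfip_wfnc")) return(x$values)
  if (is.list(x)) {
    return(do.call(rbind, lapply(x, wfnc_values)))
  }
  abort("expected a matrix, a windowed-FNC object, or a list of them.",
        class = "cddfip_shape_error")
}
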