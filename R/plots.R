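#' Plot a ddFIP basis as connectivity heatmaps
#'
#' Devectorizes each state into its symmetric network-by-network matrix and
#' shows the loadings as faceted heatmaps.
#'
#' @param object A `cddfip_basis`.
#' @param states Which states to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cddfip_basis
#' @export
autoplot.cddfip_basis <- function(object, states = seq_len(object$K), ...) {
  df <- purrr::map_dfr(states, function(k) {
    Cm <- devectorize_upper(object$states[k, ])
    tibble::tibble(
      state = paste0("state ", k),
      row = rep(seq_len(nrow(Cm)), times = ncol(Cm)),
      col = rep(seq_len(ncol(Cm)), each = nrow(Cm)),
      loading = as.numeric(Cm)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$loading)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::facet_wrap(~state) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading") +
    ggplot2::theme_minimal()
}

#' Scree plot for model-order selection
#'
#' @param order_selection Result of [select_model_order()].
#' @return A ggplot of cumulative explained variance with the selected
#'   elbow marked.
#' @export
plot_scree <- function(order_selection) {
  cv <- order_selection$curve
  ggplot2::ggplot(cv, ggplot2::aes(.data$component,
                                   .data$cumulative_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = order_selection$order,
                        linetype = "dashed") +
    ggplot2::labs(x = "components", y = "cumulative explained variance") +
    ggplot2::theme_minimal()
}

#' Plot a subject's calibrated state timecourses
#'
#' @param object A `cddfip_subject`.
#' @param ... Unused.
#' @return A ggplot of amplitude versus window, one line per state.
#' @method autoplot cddfip_subject
#' @export
autoplot.cddfip_subject <- function(object, ...) {
  df <- tidy.cddfip_subject(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$window, .data$amplitude,
                                   colour = factor(.data$state))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(colour = "state", y = "calibrated amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a group comparison as a signed-log significance matrix
#'
#' For comparisons over state pairs, reshapes the signed `-log10(p)` values
#' into the symmetric state-by-state matrix and marks FDR-significant cells.
#'
#' @param object A `cddfip_comparison` whose features are `i-j` pair
#'   labels.
#' @param ... Unused.
#' @return A ggplot heatmap.
#' @method autoplot cddfip_comparison
#' @export
autoplot.cddfip_comparison <- function(object, ...) {
  parts <- strsplit(object$feature, "-", fixed = TRUE)
  if (all(lengths(parts) == 2)) {
    df <- tibble::tibble(
      i = as.integer(vapply(parts, `[`, "", 1)),
      j = as.integer(vapply(parts, `[`, "", 2)),
      value = object$signed_log10,
      significant = object$significant
    )
    df <- dplyr::bind_rows(df, dplyr::rename(df, i = "j", j = "i"))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i,
                                          fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::geom_point(data = dplyr::filter(df, .data$significant),
                          shape = 8, size = 1) +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_equal() +
      ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                    high = "#b2182b") +
      ggplot2::labs(fill = "-log10(p) * sign(t)")
  } else {
    df <- tibble::tibble(feature = factor(object$feature,
                                          levels = object$feature),
                         value = object$signed_log10,
                         significant = object$significant)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$value,
                                          fill = .data$significant)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "-log10(p) * sign(t)", fill = "q < threshold")
  }
  p + ggplot2::theme_minimal()
}

#' Plot group-average state-density distributions
#'
#' @param dynamics List of `cddfip_dynamics` (one per subject).
#' @param groups Character vector of group labels, one per subject.
#' @return A ggplot of the mean density pdf per group.
#' @export
plot_state_density <- function(dynamics, groups) {
  stopifnot(length(dynamics) == length(groups))
  df <- purrr::map_dfr(unique(groups), function(g) {
    pdfs <- lapply(dynamics[groups == g], function(d) d$density)
    m <- group_mean_density(pdfs)
    tibble::tibble(group = g, k = seq_along(m) - 1L, probability = m)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$probability,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "number of strong states", y = "probability") +
    ggplot2::theme_minimal()
}
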