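# dendrogram segment coordinates for ggplot rendering
hclust_segments <- function(hc) {
  m <- hc$merge
  n <- nrow(m) + 1
  xpos <- numeric(nrow(m))
  segs <- list()
  node_x <- function(child, i) {
    if (child < 0) match(-child, hc$order) else xpos[child]
  }
  node_h <- function(child) if (child < 0) 0 else hc$height[child]
  for (i in seq_len(nrow(m))) {
    x1 <- node_x(m[i, 1]); x2 <- node_x(m[i, 2])
    h1 <- node_h(m[i, 1]); h2 <- node_h(m[i, 2])
    h <- hc$height[i]
    segs[[length(segs) + 1]] <- tibble::tibble(
      x = c(x1, x2, x1), xend = c(x1, x2, x2),
      y = c(h1, h2, h), yend = c(h, h, h))
    xpos[i] <- (x1 + x2) / 2
  }
  dplyr::bind_rows(segs)
}

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' the clustering dendrogram with group colours, the property-comparison
#' table as signed -log10 p-values, and the cutoff sweep as design counts
#' against median marker spacing.
#'
#' @param object A `kasp_clusters`, `kasp_property_comparison` or
#'   `kasp_cutoff_sweep` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name autoplot-kaspforge
NULL

#' @rdname autoplot-kaspforge
#' @importFrom ggplot2 autoplot
#' @method autoplot kasp_clusters
#' @export
autoplot.kasp_clusters <- function(object, ...) {
  hc <- object$hclust
  segs <- hclust_segments(hc)
  leaves <- tibble::tibble(
    x = seq_along(hc$order),
    sample = hc$labels[hc$order],
    cluster = factor(object$labels[hc$labels[hc$order]])
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend),
                          linewidth = 0.3) +
    ggplot2::geom_point(data = leaves,
                        ggplot2::aes(x = .data$x, y = 0,
                                     colour = .data$cluster), size = 0.8) +
    ggplot2::labs(x = NULL, y = "height", colour = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @rdname autoplot-kaspforge
#' @method autoplot kasp_property_comparison
#' @export
autoplot.kasp_property_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::mutate(
      direction = ifelse(.data$mean_failure > .data$mean_success,
                         "higher in failures", "higher in successes"),
      neglogp = -log10(pmax(.data$p_value, 1e-300))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$neglogp,
    y = stats::reorder(.data$property, .data$neglogp),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = expression(-log[10] ~ italic(P)), y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-kaspforge
#' @method autoplot kasp_cutoff_sweep
#' @export
autoplot.kasp_cutoff_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cutoff))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_designs), width = 0.6,
                      fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(
      y = .data$median_spacing * max(df$n_designs) /
        max(df$median_spacing, na.rm = TRUE)), colour = "firebrick") +
    ggplot2::labs(x = "maximum ambiguous bases per flank",
                  y = "designs retained (bars); median spacing (points, rescaled)") +
    ggplot2::theme_minimal()
}

#' Call-rate histogram
#'
#' Distribution of per-marker call rates with the validation threshold
#' marked.
#'
#' @param summary A [call_rate_summary()] result.
#' @return A ggplot object.
#' @export
plot_call_rates <- function(summary) {
  stopifnot(inherits(summary, "call_rate_summary"))
  ggplot2::ggplot(summary$markers, ggplot2::aes(x = .data$call_rate)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = summary$threshold, linetype = 2) +
    ggplot2::labs(x = "per-marker call rate", y = "markers") +
    ggplot2::theme_minimal()
}
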