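#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Skewness plot of per-gene AT/GC skew against content
#'
#' @param object A `skew_points` tibble from [skew_points()].
#' @param variant `"AT"`, `"GC"` or `"both"` (facetted).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_skew <- function(object, variant = c("both", "AT", "GC"), ...) {
  variant <- match.arg(variant)
  df <- if (variant == "both") object else dplyr::filter(object, .data$variant == !!variant)
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$content_pct, .data$skew,
                                         colour = .data$gene)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Content (%)", y = "Skew", colour = "Gene") +
    ggplot2::theme_minimal()
  if (variant == "both") gg <- gg + ggplot2::facet_wrap(~variant, scales = "free_x")
  gg
}

#' @exportS3Method ggplot2::autoplot
autoplot.skew_points <- function(object, ...) plot_skew(object, ...)

#' ENC plot: ENC against GC3 with the mutation-only standard curve
#'
#' @param object An `enc_points` tibble from [enc_plot_points()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_enc <- function(object, ...) {
  curve <- attr(object, "curve") %||% enc_standard_curve()
  key <- intersect(names(object), c("gene", "unit_id", "record_id"))[1]
  ggplot2::ggplot(object, ggplot2::aes(.data$gc3, .data$enc)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(.data$gc3, .data$expected_enc),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[key]])) +
    ggplot2::labs(x = "GC3", y = "ENC", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.enc_points <- function(object, ...) plot_enc(object, ...)

#' PR2 bias plot at third positions of four-fold degenerate codons
#'
#' @param object A `pr2_points` tibble from [pr2_points()].
#' @param ... Unused.
#' @return A ggplot with x = G3/(G3+C3), y = A3/(A3+T3) and the neutral
#'   centre (0.5, 0.5) marked.
#' @export
plot_pr2 <- function(object, ...) {
  key <- intersect(names(object), c("gene", "unit_id", "record_id"))[1]
  ggplot2::ggplot(object, ggplot2::aes(.data$gc_bias, .data$at_bias,
                                       colour = .data[[key]])) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "G3/(G3+C3)", y = "A3/(A3+T3)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pr2_points <- function(object, ...) plot_pr2(object, ...)

#' Heatmap of per-gene RSCU profiles
#'
#' @param mean_tbl A per-gene `rscu_tbl` (e.g. from [mean_rscu()]).
#' @return A ggplot tile map, codons on the y axis in codon-table order.
#' @export
plot_rscu_heatmap <- function(mean_tbl) {
  key <- intersect(names(mean_tbl), c("gene", "unit_id"))[1]
  df <- dplyr::mutate(mean_tbl,
                      codon = factor(.data$codon, levels = rev(codon_levels())))
  ggplot2::ggplot(df, ggplot2::aes(.data[[key]], .data$codon,
                                   fill = dplyr::coalesce(.data$rscu, 0))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  midpoint = 1, name = "RSCU") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rscu_clust <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  # segment coordinates from the merge history
  seg <- dendro_segments(dend)
  labs <- tibble::tibble(label = hc$labels[hc$order],
                         x = seq_along(hc$order))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(.data$x, -max(seg$y) * 0.02, label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(name = paste0("Height (", object$distance, ", ",
                                              object$linkage, ")")) +
    ggplot2::scale_x_continuous(breaks = NULL, name = NULL) +
    ggplot2::expand_limits(y = -max(seg$y) * 0.3) +
    ggplot2::theme_minimal()
}

dendro_segments <- function(dend) {
  segs <- list()
  leaf_pos <- 0L
  walk2 <- function(node) {
    if (stats::is.leaf(node)) {
      leaf_pos <<- leaf_pos + 1L
      return(list(x = leaf_pos, y = 0))
    }
    h <- attr(node, "height")
    kids <- lapply(seq_along(node), function(i) walk2(node[[i]]))
    xs <- vapply(kids, function(k) k$x, numeric(1))
    ys <- vapply(kids, function(k) k$y, numeric(1))
    for (i in seq_along(kids)) {
      segs[[length(segs) + 1L]] <<- tibble::tibble(x = xs[i], y = ys[i], xend = xs[i], yend = h)
    }
    segs[[length(segs) + 1L]] <<- tibble::tibble(x = min(xs), y = h, xend = max(xs), yend = h)
    list(x = mean(range(xs)), y = h)
  }
  walk2(dend)
  dplyr::bind_rows(segs)
}
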