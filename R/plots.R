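#' Plot repeat coverage along a genome
#'
#' Tandem, dispersed and union coverage drawn as stacked interval tracks.
#'
#' @param object A `repeat_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repeat_report <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component,
                         levels = c("union", "dispersed", "tandem"))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = as.integer(.data$component) - 0.4,
                                    ymax = as.integer(.data$component) + 0.4,
                                    fill = .data$component)) +
    ggplot2::scale_y_continuous(breaks = 1:3,
                                labels = levels(df$component),
                                limits = c(0.5, 3.5)) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = sprintf("%s: %.1f%% repetitive",
                                  object$genome_id, object$repeat_pct)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot the hit-length spectrum of a shared-DNA comparison
#'
#' @param object A `shared_dna` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shared_dna <- function(object, bins = 30, ...) {
  hits <- tidy(object)
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hit length (bp)", y = "hits",
                  title = sprintf("%s vs %s: %d hits, %.1f kb shared",
                                  object$query_id, object$subject_id,
                                  object$stats$n, object$merged_total_kb)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted gene-copy tree
#'
#' Nuclear copies are highlighted; bootstrap support (when computed) is
#' shown at internal nodes.  Uses ape's phylogram layout.
#'
#' @param x A `copy_tree`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot_copy_tree <- function(x, ...) {
  stopifnot(inherits(x, "copy_tree"))
  comp <- stats::setNames(x$aln$compartment, x$aln$label)
  cols <- ifelse(comp[x$tree$tip.label] == "nuclear", "black", "brown")
  ape::plot.phylo(x$tree, tip.color = cols, ...)
  if (!is.null(x$support)) {
    ape::nodelabels(x$support, frame = "none", cex = 0.7, adj = c(1.2, -0.3))
  }
  invisible(x)
}
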