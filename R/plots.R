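#' Plot the conservation-score distribution of a consensus TAD run
#'
#' Histogram of the conservation score over all basis TADs, with the score
#' threshold marked; conserved calls concentrate to its right.
#'
#' @param object A `tad_consensus` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tad_consensus
#' @export
autoplot.tad_consensus <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$config$score_threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "conservation score S", y = "basis TADs",
                  title = sprintf("%d / %d TADs conserved",
                                  nrow(object$tads), nrow(object$scores))) +
    ggplot2::theme_minimal()
}

#' Plot the null distribution of a placement test
#'
#' Histogram of the simulated statistic with the observed value marked.
#'
#' @param object A `placement_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot placement_test
#' @export
autoplot.placement_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = object$statistic, y = "simulations",
      title = sprintf("observed %.4g vs null (MC p = %.3g)",
                      object$observed, object$mc_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a body-part enrichment profile
#'
#' Enrichment ratio per organ, coloured by FDR < 0.05 significance -- the
#' single-list analogue of an enrichment heat map.
#'
#' @param object An `organ_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot organ_enrichment
#' @export
autoplot.organ_enrichment <- function(object, ...) {
  d <- tidy(object) |>
    mutate(organ = factor(.data$organ, levels = rev(.data$organ)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$enrichment_ratio, y = .data$organ,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70"),
                               name = "FDR < 0.05") +
    ggplot2::labs(x = "enrichment ratio (observed / expected)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of DMR distances to the closest TAD boundary
#'
#' @param boundary_table Output of [dmr_boundary_table()].
#' @param cutoff Proximity cut-off to mark (default 50 kb).
#' @return A ggplot object.
#' @export
plot_boundary_distances <- function(boundary_table, cutoff = 50000) {
  ggplot2::ggplot(boundary_table, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey35") +
    ggplot2::geom_vline(xintercept = cutoff, colour = "red") +
    ggplot2::labs(x = "distance to closest TAD boundary (bp)", y = "DMRs") +
    ggplot2::theme_minimal()
}
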