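# ggplot2 views of the main result types.

#' Plot identity-score distributions by pair class
#'
#' Histograms of pairwise identity scores split by pair class, with the
#' authentication threshold marked: replicates and same-patient
#' derivatives should sit to the right of the line, unrelated pairs well
#' to its left.
#'
#' @param pairs Pairwise score tibble from [pairwise_identity()].
#' @param threshold Identity threshold to mark (default 0.90).
#' @param bins Histogram bins (default 60).
#' @return A ggplot object.
#' @export
plot_identity_distribution <- function(pairs, threshold = 0.9, bins = 60) {
  pairs <- pairs[!is.na(pairs$score), ]
  ggplot2::ggplot(pairs, ggplot2::aes(x = score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(pair_class), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "identity score", y = "pairs") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cellauth_sensitivity <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("fraction", "identity_vs_host",
                                  "identity_vs_contaminant")],
    cols = -fraction, names_to = "reference", values_to = "identity",
    names_prefix = "identity_vs_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = fraction, y = identity,
                                     colour = reference)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("fraction of %s in the mixture", attr(object, "contaminant")),
      y = "identity score",
      colour = "scored against"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cellauth_subset_power <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(k), y = sd_score)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::geom_hline(yintercept = attr(object, "full_sd"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "markers per subset", y = "SD of unrelated-pair scores") +
    ggplot2::theme_minimal()
}
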