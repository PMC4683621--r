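#' Plot category counts of a classification
#'
#' Bar chart of the number of proteins per category, with the substrate
#' subset of the trap-specific bar highlighted.
#'
#' @param object A [classify_proteins()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trap_classification <- function(object, ...) {
  d <- as_tibble(object) %>%
    count(.data$category, .data$substrate, .drop = FALSE, name = "n") %>%
    filter(!(.data$n == 0 & .data$substrate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n,
                                  fill = .data$substrate)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "#c0392b"),
                               name = "potential substrate") +
    ggplot2::labs(x = NULL, y = "proteins",
                  title = "Substrate-trapping classification") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a recovery confusion matrix
#'
#' Tile plot of planted role versus assigned category from an evaluation
#' against simulated ground truth.
#'
#' @param object An [evaluate_classification()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trap_evaluation <- function(object, ...) {
  d <- object$confusion
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$role,
                                  fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8", name = "proteins") +
    ggplot2::labs(x = "assigned category", y = "planted role",
                  title = "Recovery of planted roles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Scatter plot of per-sample evidence underlying the classification
#'
#' Mean unique peptides in the reference-bait sample against the trap-bait
#' sample, one point per protein, coloured by category — the visual
#' counterpart of the trap-vs-reference comparison.
#'
#' @param x A [classify_proteins()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_bait_evidence <- function(x, ...) {
  stopifnot(inherits(x, "trap_classification"))
  ggplot2::ggplot(as_tibble(x),
                  ggplot2::aes(x = .data$mean_unique_reference,
                               y = .data$mean_unique_trap,
                               colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "mean unique peptides, reference bait",
                  y = "mean unique peptides, trap bait",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
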