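# ggplot2 displays for the package's result objects.

#' Heatmap of the pairwise pi1 dissimilarity matrix
#'
#' @param object A `promiso_pi1` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.promiso_pi1 <- function(object, ...) {
  tidy(object) %>%
    ggplot2::ggplot(ggplot2::aes(.data$region_a, .data$region_b,
                                 fill = .data$pi1)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$pi1)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(pi[1])) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise statistical dissimilarity") +
    ggplot2::theme_minimal()
}

#' Library-size and normalization-factor overview
#'
#' @param object A `promiso_expr` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.promiso_expr <- function(object, ...) {
  object$factors %>%
    ggplot2::ggplot(ggplot2::aes(.data$lib_size, .data$norm_factor,
                                 label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "library size", y = "TMM factor",
                  title = sprintf("%s normalization", object$feature_kind)) +
    ggplot2::theme_minimal()
}

#' ABC score versus enhancer-promoter distance
#'
#' @param links Link tibble from [abc_scores()].
#' @return A ggplot.
#' @export
plot_abc_links <- function(links) {
  links %>%
    ggplot2::ggplot(ggplot2::aes(.data$distance_bp / 1e3, .data$abc,
                                 colour = .data$kind)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "element-TSS distance (kb)", y = "ABC score") +
    ggplot2::theme_minimal()
}

#' Priority-score distributions of fine-mapped target classes
#'
#' Compares the priority scores of genes reached via 5' and non-5'
#' promoter-isoform links.
#'
#' @param assignments Output of [assign_targets()] (scores required).
#' @return A ggplot.
#' @export
plot_target_scores <- function(assignments) {
  if (!"priority_score" %in% names(assignments)) {
    abort("assignments carry no priority scores")
  }
  assignments %>%
    distinct(.data$gene_id, .data$promoter_type, .data$priority_score) %>%
    ggplot2::ggplot(ggplot2::aes(.data$promoter_type, .data$priority_score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "priority score") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
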