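#' Plot class-association enrichment as log odds ratios
#'
#' Bar panel per species of the log conditional-MLE odds ratio by category;
#' categories untestable in a species have no bar, and bars passing the FDR
#' threshold are filled.
#'
#' @param object A `como_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.como_enrichment <- function(object, ...) {
  d <- object[object$tested & is.finite(object$log_or), ]
  d$category <- factor(d$category, levels = rev(mcat_categories()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_or, y = .data$category,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species), nrow = 1) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey70"),
                               name = "q < 0.05") +
    ggplot2::labs(x = "log odds ratio (conditional MLE)", y = NULL)
}

#' Plot the distribution of per-gene cross-species ICC values
#'
#' @param object A `como_icc` tibble.
#' @param alpha Significance threshold marked on the histogram legend.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.como_icc <- function(object, alpha = 1e-3, ...) {
  d <- dplyr::mutate(object, significant = .data$p_perm <= alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$icc, fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = stats::median(d$icc), linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                               name = paste0("perm. p < ", format(alpha))) +
    ggplot2::labs(x = "intraclass correlation coefficient", y = "genes")
}

#' Plot a gap-statistic curve
#'
#' @param gap Result of [select_k_gap()].
#' @return A ggplot of gap(k) with one-standard-error bars and the chosen k
#'   marked.
#' @export
plot_gap_curve <- function(gap) {
  d <- gap$gap_curve
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$se,
                                          ymax = .data$gap + .data$se)) +
    ggplot2::geom_vline(xintercept = gap$chosen_k, linetype = 2,
                        colour = "#b2182b") +
    ggplot2::labs(x = "k", y = "gap statistic")
}

#' Plot mouse-human phenotype correlation against human phenotype load
#'
#' @param object A `como_correlation` tibble.
#' @param ... Unused.
#' @return A ggplot (log10 y axis; genes with zero human phenotypes are
#'   dropped from the plot, as only annotated genes are informative here).
#' @export
autoplot.como_correlation <- function(object, ...) {
  d <- object[object$n_human_phenotypes > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$n_human_phenotypes,
                                  colour = .data$substituted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey60", `FALSE` = "#2166ac"),
                                 name = "r = 0 substituted") +
    ggplot2::labs(x = "mouse-human Pearson r", y = "human phenotypes per gene")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
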