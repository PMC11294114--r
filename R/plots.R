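# ggplot2 views of the main result types.

#' Volcano plot of a differential-expression result
#'
#' @param object An `l1r_de` tibble from [wald_test()].
#' @param alpha Adjusted p-value cutoff used for colouring (default 0.1).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.l1r_de <- function(object, alpha = 0.1, ...) {
  df <- object[!object$filtered & !is.na(object$p), , drop = FALSE]
  df$significant <- !is.na(df$padj) & df$padj <= alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = paste0("padj ≤ ", alpha)) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 raw p") +
    ggplot2::theme_minimal()
}

#' Dot plot of an over-representation result
#'
#' Gene ratio (overlap / query size) per set, dot size the overlap count,
#' colour the adjusted p-value — the standard enrichment dot plot.
#'
#' @param object An `l1r_enrich` tibble from [enrich_sets()].
#' @param top Number of top sets (by p) shown.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.l1r_enrich <- function(object, top = 20, ...) {
  df <- utils::head(object[order(object$p), , drop = FALSE], top)
  df$set_id <- factor(df$set_id, levels = rev(df$set_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_ratio, y = .data$set_id,
                                   size = .data$k, colour = .data$padj)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "steelblue") +
    ggplot2::labs(x = "gene ratio", y = NULL, size = "overlap", colour = "padj") +
    ggplot2::theme_minimal()
}

#' Discrimination-index plot by group
#'
#' Jittered per-mouse values of a DI metric with group means.
#'
#' @param behavior A behaviour tibble (DI columns added if needed).
#' @param metric `"delta_di"`, `"di_4m"` or `"di_baseline"`.
#' @return A ggplot object.
#' @export
plot_di <- function(behavior, metric = "delta_di") {
  behavior <- add_di(behavior)
  ggplot2::ggplot(behavior, ggplot2::aes(x = .data$group, y = .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' L1 transcript fraction by group
#'
#' @param fractions A tibble from [l1_fraction()].
#' @param samples A sample sheet with a `group` column.
#' @return A ggplot object.
#' @export
plot_l1_fraction <- function(fractions, samples) {
  if (!"group" %in% names(samples)) {
    samples$group <- group_label(samples$genotype, samples$treatment)
  }
  df <- dplyr::left_join(fractions, samples[, c("sample_id", "group")], by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$l1_fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "L1 fraction of transcriptome") +
    ggplot2::theme_minimal()
}
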