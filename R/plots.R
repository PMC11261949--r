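# Diagnostic plots: the volcano view of the enrichment screen, a PCA
# sanity view of the six features, and the cross-validated feature weights.

#' Volcano plot of a channel enrichment screen
#'
#' @param enrichment Tibble from [channel_enrichment()] (one or more
#'   variant classes row-bound together).
#' @param fc_threshold,fdr_log_threshold Thresholds drawn as guide lines;
#'   should match those used in the screen.
#' @return A ggplot object: log2 fold change against -log10 adjusted
#'   p-value, channels coloured by the group they are enriched in.
#' @export
plot_volcano <- function(enrichment, fc_threshold = 0.75,
                         fdr_log_threshold = 3) {
  df <- dplyr::mutate(enrichment,
                      neg_log10_q = -log10(pmax(.data$q_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, .data$neg_log10_q,
                                   colour = .data$enriched_in)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = fdr_log_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(HRD = "#c0392b", HRP = "#2980b9",
                                            none = "grey70")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant_class), scales = "free") +
    ggplot2::labs(x = "log2 fold change (HRD / HRP mean proportion)",
                  y = expression(-log[10] ~ "FDR-adjusted p"),
                  colour = "enriched in") +
    ggplot2::theme_minimal()
}

#' PCA view of the six features
#'
#' Principal components of the standardized feature matrix, as a sanity
#' check that the six features separate the two groups.
#'
#' @param features Feature tibble from [extract_features()].
#' @param labels `"HRD"`/`"HRP"` labels (named vector or tibble).
#' @return A ggplot object of the first two principal components.
#' @export
plot_feature_pca <- function(features, labels) {
  x <- feature_matrix(features)
  y <- resolve_labels(labels, rownames(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  var_pct <- round(100 * pc$sdev[1:2]^2 / sum(pc$sdev^2), 1)
  df <- tibble::tibble(PC1 = pc$x[, 1], PC2 = pc$x[, 2], label = y)
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(HRD = "#c0392b", HRP = "#2980b9")) +
    ggplot2::labs(x = paste0("PC1 (", var_pct[1], "%)"),
                  y = paste0("PC2 (", var_pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Bar plot of the average cross-validation feature weights
#'
#' Positive weights mark features predictive of HRD, negative weights
#' features predictive of HRP.
#'
#' @param model An `hrd_model` (or a list of them, named by panel).
#' @return A ggplot object.
#' @export
plot_feature_weights <- function(model) {
  models <- if (inherits(model, "hrd_model")) list(model = model) else model
  df <- purrr::imap_dfr(models, function(m, nm) {
    w <- feature_weights(m)
    tibble::tibble(panel = paste0(nm, " (", m$tissue, "/", m$assay, ")"),
                   feature = names(w), weight = unname(w))
  })
  df$feature <- factor(df$feature, levels = FEATURE_ORDER)
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$weight,
                                   fill = .data$weight > 0)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "#2980b9"),
                               labels = c(`TRUE` = "HRD", `FALSE` = "HRP"),
                               name = "predictive of") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel)) +
    ggplot2::labs(x = NULL, y = "mean 10-fold CV weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_feature_weights
#' @param object An `hrd_model`.
#' @param ... Unused.
#' @export
autoplot.hrd_model <- function(object, ...) plot_feature_weights(object)
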