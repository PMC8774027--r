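#' Boxplots of estimated cell-type proportions by study and condition
#'
#' @param proportions Tibble `sample_id` plus one column per cell type.
#' @param meta Metadata with `sample_id`, `study_id`, `status`.
#' @return A ggplot object.
#' @export
plot_proportions <- function(proportions, meta) {
  d <- proportions |>
    tidyr::pivot_longer(-dplyr::any_of(c("sample_id", "study_id")),
                        names_to = "celltype", values_to = "proportion") |>
    dplyr::left_join(meta[, c("sample_id", "study_id", "status")],
                     by = "sample_id", suffix = c("", ".meta"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$celltype, y = .data$proportion,
                                  fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~study_id) +
    ggplot2::labs(x = NULL, y = "Estimated proportion", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of pooled standardized mean differences per cell type
#'
#' @param object A `cyto_prop_meta` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_prop_meta <- function(object, ...) {
  d <- dplyr::mutate(object$pooled,
                     sig = ifelse(.data$p_adj < 0.05, "*", ""))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$celltype, .data$smd),
                                  y = .data$smd)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$smd - .data$se,
                                        ymax = .data$smd + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "Pooled SMD (case - control)") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression run
#'
#' @param object A `cyto_de` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_de <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$beta_status,
                               y = -log10(pmax(.data$p_adj, 1e-300)),
                               colour = .data$deg_call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Status coefficient (log2 FC)",
                  y = "-log10 adjusted p", colour = "DEG") +
    ggplot2::theme_minimal()
}

#' Lollipop plot of top enriched gene sets
#'
#' @param object A `cyto_gsea` table.
#' @param n Number of top sets (by adjusted p) to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_gsea <- function(object, n = 10, ...) {
  d <- utils::head(dplyr::arrange(tibble::as_tibble(object), .data$p_adj), n)
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(pmax(.data$p_adj, 1e-300)),
                                  y = stats::reorder(.data$set_id, -.data$p_adj),
                                  colour = .data$nes)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::scale_colour_gradient2(low = "navy", high = "firebrick") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, colour = "NES") +
    ggplot2::theme_minimal()
}

#' Bar plot of EWCE enrichment z-scores per cell type
#'
#' @param object A `cyto_ewce` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_ewce <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     label = sprintf("(%.3g)", .data$p_adj))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$celltype, y = .data$z)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "SDs from random-list mean") +
    ggplot2::theme_minimal()
}
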