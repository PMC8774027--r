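#' Tidy a cell-proportion meta-analysis
#'
#' @param x A `cyto_prop_meta` object from [prop_meta()].
#' @param which `"pooled"` (default) or `"per_study"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cyto_prop_meta <- function(x, which = c("pooled", "per_study"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname tidy.cyto_prop_meta
#' @export
glance.cyto_prop_meta <- function(x, ...) {
  tibble::tibble(n_celltypes = nrow(x$pooled),
                 k_studies = max(x$pooled$k_studies),
                 n_significant = sum(x$pooled$p_adj < 0.05),
                 max_tau2 = max(x$pooled$tau2))
}

#' Tidy / summarise a differential-expression run
#'
#' @param x A `cyto_de` table from [run_de()].
#' @param ... Unused.
#' @return `tidy()` returns the table as a plain tibble; `glance()` a
#'   one-row summary (genes fitted, skipped, DEGs up/down).
#' @export
tidy.cyto_de <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.cyto_de
#' @export
glance.cyto_de <- function(x, ...) {
  skipped <- attr(x, "skipped")
  tibble::tibble(mode = attr(x, "mode"), n_genes = nrow(x),
                 n_skipped = if (is.null(skipped)) 0L else nrow(skipped),
                 n_deg = sum(x$deg_call),
                 n_up = sum(x$deg_call & x$direction == "up"),
                 n_down = sum(x$deg_call & x$direction == "down"))
}

#' Tidy / summarise a GSEA result
#'
#' @param x A `cyto_gsea` table.
#' @param ... Unused.
#' @export
tidy.cyto_gsea <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.cyto_gsea
#' @export
glance.cyto_gsea <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x), n_significant = sum(x$p_adj < 0.05),
                 n_up = sum(x$p_adj < 0.05 & x$es > 0),
                 n_down = sum(x$p_adj < 0.05 & x$es < 0))
}

#' Tidy / summarise an EWCE result
#'
#' @param x A `cyto_ewce` table.
#' @param ... Unused.
#' @export
tidy.cyto_ewce <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.cyto_ewce
#' @export
glance.cyto_ewce <- function(x, ...) {
  tibble::tibble(n_celltypes = nrow(x), n_used = x$n_used[1],
                 n_significant = sum(x$p_adj < 0.05),
                 top_type = x$celltype[which.min(x$p)])
}
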