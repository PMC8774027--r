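#' Average single-cell expression by annotated cell type
#'
#' Arithmetic mean per cell type over its cells, on the linear scale. If the
#' matrix is flagged as log-scale it is un-logged (2^x - pseudo handling is
#' the caller's concern; we assume log2(x) with no pseudo-count offset worth
#' correcting at averaging resolution).
#'
#' @param m Cells x genes numeric matrix.
#' @param clusters Cluster label per cell (length `nrow(m)`).
#' @param annotations Named character vector: cluster -> cell type. Every
#'   cluster must be annotated; an annotated type with zero cells errors.
#' @param log_scale Is `m` on log2 scale? If `TRUE`, un-logged before
#'   averaging.
#' @return Cell types x genes matrix of mean linear-scale expression.
#' @export
average_by_type <- function(m, clusters, annotations, log_scale = FALSE) {
  m <- as.matrix(m)
  if (length(clusters) != nrow(m)) {
    rlang::abort("`clusters` must have one label per cell (row of `m`).")
  }
  clusters <- as.character(clusters)
  if (!all(clusters %in% names(annotations))) {
    rlang::abort("Every cluster needs an entry in `annotations`.")
  }
  types <- unique(unname(annotations))
  cell_type <- unname(annotations[clusters])
  missing_types <- setdiff(types, cell_type)
  if (length(missing_types)) {
    rlang::abort(sprintf("Annotated type(s) with zero cells: %s",
                         paste(missing_types, collapse = ", ")))
  }
  if (log_scale) m <- 2^m
  out <- rowsum(m, cell_type) / as.vector(table(cell_type)[sort(unique(cell_type))])
  out[types, , drop = FALSE]
}

#' Find cluster marker genes by detection rate and log fold change
#'
#' A gene marks a cluster when it is detected (value strictly > 0) in at
#' least `min_frac` of the cluster's cells and the log fold change of the
#' cluster's mean over the mean of all other cells exceeds `min_lfc`. The
#' log fold change is the natural-log ratio of linear-scale means with a
#' 1e-9 pseudo-count by default; set `log_base = 2` for log2 ratios.
#'
#' @param m Cells x genes matrix, linear scale (un-log first if needed).
#' @param clusters Cluster label per cell.
#' @param min_frac Minimum detection fraction within the cluster.
#' @param min_lfc Minimum log fold change (strict).
#' @param log_base Base of the fold-change logarithm.
#' @return Named list: cluster -> character vector of marker genes.
#' @export
find_markers <- function(m, clusters, min_frac = 0.30, min_lfc = 0.5,
                         log_base = exp(1)) {
  m <- as.matrix(m)
  clusters <- as.character(clusters)
  if (length(unique(clusters)) < 2) {
    rlang::abort("Marker finding needs at least 2 clusters.")
  }
  eps <- 1e-9
  out <- lapply(sort(unique(clusters)), function(cl) {
    inc <- clusters == cl
    det <- colMeans(m[inc, , drop = FALSE] > 0)
    mu_in <- colMeans(m[inc, , drop = FALSE])
    mu_out <- colMeans(m[!inc, , drop = FALSE])
    lfc <- log(mu_in + eps, base = log_base) - log(mu_out + eps, base = log_base)
    colnames(m)[det >= min_frac & lfc > min_lfc]
  })
  stats::setNames(out, sort(unique(clusters)))
}

#' Cell-type expression specificity
#'
#' A gene's specificity for a type is its mean expression there divided by
#' its summed mean expression over all types, so each retained gene's
#' specificities sum to one. Genes with zero total expression are dropped
#' and reported via the `dropped` attribute.
#'
#' @param avg Cell types x genes non-negative matrix (see
#'   [average_by_type()]).
#' @return Cell types x genes specificity matrix with values in \[0, 1\].
#' @export
specificity <- function(avg) {
  avg <- as.matrix(avg)
  if (any(avg < 0)) rlang::abort("`avg` must be non-negative.")
  tot <- colSums(avg)
  dropped <- colnames(avg)[tot == 0]
  keep <- tot > 0
  s <- sweep(avg[, keep, drop = FALSE], 2, tot[keep], "/")
  attr(s, "dropped") <- dropped
  s
}
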