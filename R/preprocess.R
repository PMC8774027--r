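#' Collapse probes to genes by variance + connectivity
#'
#' For genes measured by several probes, keeps the probe maximizing
#' `rank(variance across samples) + rank(connectivity)`, where connectivity
#' is the sum of absolute Pearson correlations with the gene's other probes
#' (zero for single-probe genes). Unmapped probes are dropped. Rank ties are
#' broken by the lexicographically smallest probe id so builds are
#' deterministic.
#'
#' @param mat Probes x samples numeric matrix with probe rownames.
#' @param probe_map Data frame with columns `probe_id`, `gene_id`; a probe
#'   may appear at most once.
#' @return Genes x samples matrix, one row per mapped gene, with an
#'   attribute `chosen_probes` (named character: gene -> winning probe).
#' @export
collapse_probes <- function(mat, probe_map) {
  check_named_matrix(mat, "mat")
  probe_map <- tibble::as_tibble(probe_map)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map)) ||
      nrow(probe_map) == 0) {
    rlang::abort("`probe_map` needs nonempty `probe_id` and `gene_id` columns.")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    rlang::abort("A probe maps to more than one gene in `probe_map`.")
  }
  probe_map <- dplyr::filter(probe_map, .data$probe_id %in% rownames(mat))
  if (nrow(probe_map) == 0) {
    rlang::abort("No probe in `mat` is present in `probe_map`.")
  }
  pick <- probe_map |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(d, key) {
      probes <- sort(d$probe_id)
      if (length(probes) == 1L) return(c(key$gene_id, probes))
      sub <- mat[probes, , drop = FALSE]
      v <- apply(sub, 1, stats::var)
      cc <- abs(stats::cor(t(sub)))
      conn <- rowSums(cc) - 1  # drop self-correlation
      score <- rank(v, ties.method = "average") +
        rank(conn, ties.method = "average")
      c(key$gene_id, probes[which.max(score)])  # which.max -> first = smallest id
    })
  genes <- vapply(pick, `[`, character(1), 1L)
  probes <- vapply(pick, `[`, character(1), 2L)
  out <- mat[probes, , drop = FALSE]
  rownames(out) <- genes
  out <- out[order(genes), , drop = FALSE]
  attr(out, "chosen_probes") <- stats::setNames(probes[order(genes)], sort(genes))
  out
}

#' Quantile normalization across samples
#'
#' Forces every column's distribution onto the across-column mean of order
#' statistics. Genes missing for a sample (e.g. not probed on that study's
#' platform) are excluded from that column's quantile computation and remain
#' missing: values are never fabricated for unprobed genes. Ties within a
#' column receive the mean of the target values at their tied ranks.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat Genes x samples matrix (log scale), `NA` allowed.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  check_named_matrix(mat, "mat")
  if (ncol(mat) < 2) rlang::abort("Quantile normalization needs >= 2 columns.")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Impute sample sex from Y-linked gene expression
#'
#' Keeps the top `variable_fraction` most variable of the Y-linked genes
#' present in the matrix, 2-means clusters the samples on them, and labels
#' the cluster with lower mean Y expression "F". Samples with a known
#' annotation are passed through unchanged.
#'
#' @param mat Genes x samples matrix.
#' @param y_genes Character vector of Y-linked gene ids (>= 2 must be present).
#' @param variable_fraction Fraction of present Y genes kept, by variance.
#' @param annotated Optional named character vector (sample -> "F"/"M");
#'   non-missing entries override the imputation.
#' @return Tibble `sample_id`, `gender`, `imputed` (logical), with attribute
#'   `low_confidence` set when the two cluster means differ by less than 10%
#'   of the pooled SD of the clustering features.
#' @export
impute_gender <- function(mat, y_genes, variable_fraction = 0.75,
                          annotated = NULL) {
  check_named_matrix(mat, "mat")
  if (ncol(mat) < 2) rlang::abort("Need at least 2 samples.")
  present <- intersect(y_genes, rownames(mat))
  if (length(present) < 2) {
    rlang::abort("Fewer than 2 Y-linked genes present in the matrix.")
  }
  y <- mat[present, , drop = FALSE]
  v <- apply(y, 1, stats::var)
  keep <- names(sort(v, decreasing = TRUE))[
    seq_len(max(1L, round(variable_fraction * length(present))))]
  feats <- t(y[keep, , drop = FALSE])
  centers <- rbind(apply(feats, 2, min), apply(feats, 2, max))
  low_conf <- FALSE
  if (all(centers[1, ] == centers[2, ])) {
    # degenerate: all samples identical on Y features
    cl <- rep(1L, nrow(feats)); mu <- c(mean(feats), mean(feats))
    low_conf <- TRUE
    labels <- rep("F", nrow(feats))
  } else {
    km <- stats::kmeans(feats, centers = centers)
    cl <- km$cluster
    if (any(tabulate(cl, 2) == 0)) rlang::abort("A sex cluster is empty.")
    mu <- tapply(rowMeans(feats), cl, mean)
    pooled_sd <- stats::sd(as.vector(feats))
    if (pooled_sd == 0 || abs(diff(mu)) < 0.1 * pooled_sd) {
      low_conf <- TRUE
      rlang::warn("Low-confidence sex imputation: Y clusters barely separated.")
    }
    f_cluster <- as.integer(names(mu)[which.min(mu)])
    labels <- ifelse(cl == f_cluster, "F", "M")
  }
  out <- tibble::tibble(sample_id = colnames(mat), gender = unname(labels),
                        imputed = TRUE)
  if (!is.null(annotated)) {
    known <- annotated[!is.na(annotated) & annotated %in% c("F", "M")]
    hit <- out$sample_id %in% names(known)
    out$gender[hit] <- unname(known[out$sample_id[hit]])
    out$imputed[hit] <- FALSE
  }
  attr(out, "low_confidence") <- low_conf
  out
}
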