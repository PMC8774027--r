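#' Expression-weighted cell-type enrichment bootstrap
#'
#' Tests whether a gene list's mean cell-type specificity exceeds that of
#' random gene lists of the same size. For each cell type, the observed mean
#' specificity of the (deduplicated, matrix-present) input genes is compared
#' with `n_boot` equally sized sets sampled uniformly without replacement
#' from all genes in the specificity matrix:
#' `p = (1 + #{bootstrap mean >= observed}) / (1 + n_boot)` (one-sided,
#' enrichment only) and `z = (observed - bootstrap mean) / bootstrap SD` —
#' the "standard deviations from the random-list mean" effect size.
#' Benjamini-Hochberg correction is applied across cell types.
#'
#' @param genes Character vector of gene ids; duplicates are removed, genes
#'   absent from `s` are dropped and counted.
#' @param s Specificity matrix, cell types x genes (see [specificity()]).
#' @param n_boot Number of bootstrap lists.
#' @param seed Integer seed; fixed seed gives identical results.
#' @return Tibble of class `cyto_ewce`: `celltype`, `observed`, `boot_mean`,
#'   `boot_sd`, `z`, `p`, `p_adj`, `n_used`; attribute `n_dropped`.
#' @export
ewce_test <- function(genes, s, n_boot = 10000, seed = 1L) {
  if (!is.matrix(s)) rlang::abort("`s` must be a cell types x genes matrix.")
  genes <- unique(genes)
  used <- intersect(genes, colnames(s))
  n_dropped <- length(genes) - length(used)
  if (!length(used)) rlang::abort("No input gene is present in the specificity matrix.")
  m <- length(used)
  observed <- rowMeans(s[, used, drop = FALSE])
  boot <- withr::with_seed(as.integer(seed), {
    draws <- vapply(seq_len(n_boot),
                    function(i) sample.int(ncol(s), m), integer(m))
    # n_boot x celltype matrix of bootstrap means, one vectorized pass per type
    vapply(seq_len(nrow(s)),
           function(t) colMeans(matrix(s[t, ][draws], m, n_boot)),
           numeric(n_boot))
  })
  boot_mean <- colMeans(boot)
  boot_sd <- apply(boot, 2, stats::sd)
  # a degenerate bootstrap (e.g. the list is the whole universe, so every
  # without-replacement draw is the same set) has no spread: flag, don't NaN
  degenerate <- boot_sd <= 1e-12 * (abs(boot_mean) + 1e-12)
  z <- ifelse(!degenerate, (observed - boot_mean) / boot_sd, NA_real_)
  if (anyNA(z)) rlang::warn("Degenerate bootstrap SD: z undefined for some cell types.")
  tol <- 1e-12 * (abs(observed) + 1e-12)
  p <- vapply(seq_len(nrow(s)),
              function(t) (1 + sum(boot[, t] >= observed[t] - tol[t])) /
                (1 + n_boot),
              numeric(1))
  out <- tibble::tibble(celltype = rownames(s), observed = unname(observed),
                        boot_mean = unname(boot_mean),
                        boot_sd = unname(boot_sd), z = unname(z), p = p,
                        p_adj = bh_adjust(p), n_used = m)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("cyto_ewce", class(out))
  out
}

#' Validate realized marker panels against a specificity matrix
#'
#' Runs [ewce_test()] on each cell type's realized marker set and reports,
#' per panel, whether the top-enriched (smallest adjusted p) cell type is
#' the expected one — a compact "fraction of panels enriched in the
#' expected type" summary.
#'
#' @param realized Named list: cell type -> marker genes (e.g. from
#'   [select_markers()]).
#' @param s Specificity matrix.
#' @param n_boot,seed Passed to [ewce_test()].
#' @return Tibble: `panel_type`, `top_type`, `top_p_adj`, `match`; attribute
#'   `fraction_matched`.
#' @export
validate_markers <- function(realized, s, n_boot = 10000, seed = 1L) {
  out <- purrr::imap_dfr(realized, function(gs, t) {
    res <- ewce_test(gs, s, n_boot = n_boot, seed = seed)
    top <- res[order(res$p_adj, res$p, -res$z), ][1, ]
    tibble::tibble(panel_type = t, top_type = top$celltype,
                   top_p_adj = top$p_adj, match = top$celltype == t)
  })
  attr(out, "fraction_matched") <- mean(out$match)
  out
}
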