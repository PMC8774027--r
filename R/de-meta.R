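#' Differential expression across studies with optional composition awareness
#'
#' Fits [fit_gene_lmm()] for every gene probed (non-missing) in at least two
#' studies, adjusts the Status p-values by Benjamini-Hochberg within the
#' mode, and calls DEGs at `adjusted p < alpha` and `|log2 fold change| >
#' log2(fc)` (strict inequalities). Genes probed by a single study are
#' skipped and listed in the skip report.
#'
#' @param expr Genes x samples log2 matrix (`NA` = not probed).
#' @param meta Metadata tibble (`sample_id`, `study_id`, `status`, `gender`).
#' @param proportions Tibble with `sample_id`, `neu`, `odc`; required in
#'   aware mode.
#' @param mode `"unaware"` or `"aware"`.
#' @param engine Passed to [fit_gene_lmm()].
#' @param alpha,fc DEG thresholds (see [call_degs()]).
#' @return Tibble of class `cyto_de`, sorted by adjusted p: `gene_id`,
#'   `beta_status`, `se`, `p`, `p_adj`, `n_studies_probing`, `mode`,
#'   `deg_call`, `direction`. Attributes: `skipped` (tibble of skipped genes
#'   with reasons), `mode`.
#' @export
run_de <- function(expr, meta, proportions = NULL,
                   mode = c("unaware", "aware"),
                   engine = c("reml", "lmer"), alpha = 0.05, fc = 1.2) {
  mode <- match.arg(mode); engine <- match.arg(engine)
  check_named_matrix(expr, "expr")
  meta <- tibble::as_tibble(meta)
  if (!all(colnames(expr) %in% meta$sample_id)) {
    rlang::abort("Every expression column needs a metadata row.")
  }
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  if (mode == "aware") {
    if (is.null(proportions)) rlang::abort("Aware mode requires `proportions`.")
    if (!all(meta$sample_id %in% proportions$sample_id)) {
      rlang::abort("`proportions` does not cover every sample.")
    }
  }
  skipped <- list()
  if (engine == "reml") {
    # cache the design decomposition per missingness pattern: X, its per-study
    # sufficient statistics and the singularity check are shared by all genes
    # observed in the same samples
    cache <- new.env(parent = emptyenv())
    ng <- nrow(expr)
    beta <- se <- df <- pv <- rep(NA_real_, ng)
    nst <- rep(NA_integer_, ng); dfm <- rep(NA_character_, ng)
    fitted <- rep(FALSE, ng)
    for (i in seq_len(ng)) {
      gid <- rownames(expr)[i]
      y_full <- expr[i, ]
      obs <- !is.na(y_full)
      if (length(unique(meta$study_id[obs])) < 2) {
        skipped[[gid]] <- "Gene observed in fewer than 2 studies."
        next
      }
      key <- paste(which(obs), collapse = ",")
      ctx <- cache[[key]]
      if (is.null(ctx)) {
        meta_sub <- meta[obs, ]
        X <- lmm_build_design(meta_sub, proportions, mode)
        ctx <- list(X = X, study = meta_sub$study_id,
                    st = lmm_design_stats(X, meta_sub$study_id))
        cache[[key]] <- ctx
      }
      fit <- lmm_reml_engine(ctx$X, y_full[obs], ctx$study, "statuscase",
                             st = ctx$st)
      beta[i] <- fit$beta; se[i] <- fit$se; df[i] <- fit$df; pv[i] <- fit$p
      nst[i] <- fit$n_studies; dfm[i] <- fit$df_method; fitted[i] <- TRUE
    }
    out <- tibble::tibble(gene_id = rownames(expr)[fitted],
                          beta_status = beta[fitted], se = se[fitted],
                          df = df[fitted], p = pv[fitted],
                          df_method = dfm[fitted], n_studies = nst[fitted])
  } else {
    rows <- vector("list", nrow(expr))
    for (i in seq_len(nrow(expr))) {
      gid <- rownames(expr)[i]
      res <- tryCatch(
        fit_gene_lmm(expr[i, ], meta, proportions, mode = mode, engine = engine),
        cyto_single_study = function(e) e)
      if (inherits(res, "condition")) {
        skipped[[gid]] <- conditionMessage(res)
      } else {
        rows[[i]] <- dplyr::mutate(res, gene_id = gid)
      }
    }
    out <- dplyr::bind_rows(rows)
  }
  if (!nrow(out)) rlang::abort("No gene was probed by two or more studies.")
  out <- out |>
    dplyr::mutate(p_adj = bh_adjust(.data$p), mode = mode) |>
    dplyr::rename(n_studies_probing = "n_studies") |>
    dplyr::select("gene_id", "beta_status", "se", "df", "p", "p_adj",
                  "n_studies_probing", "mode", "df_method") |>
    dplyr::arrange(.data$p_adj, .data$p, .data$gene_id)
  out <- call_degs(out, alpha = alpha, fc = fc)
  attr(out, "skipped") <- tibble::tibble(gene_id = names(skipped),
                                         reason = unlist(skipped, use.names = FALSE) %||% character())
  attr(out, "mode") <- mode
  class(out) <- c("cyto_de", class(out))
  out
}

#' Call differentially expressed genes
#'
#' Flags genes with `p_adj < alpha` and `|beta_status| > log2(fc)` (both
#' strict) and annotates the direction of change.
#'
#' @param tab A DE result table with `p_adj` and `beta_status`.
#' @param alpha Adjusted-p threshold.
#' @param fc Linear-scale fold-change threshold (applied as
#'   `|beta| > log2(fc)` on log2 coefficients).
#' @return `tab` with `deg_call` (logical) and `direction` ("up"/"down").
#' @export
call_degs <- function(tab, alpha = 0.05, fc = 1.2) {
  dplyr::mutate(tab,
    deg_call = .data$p_adj < alpha & abs(.data$beta_status) > log2(fc),
    direction = ifelse(.data$beta_status > 0, "up", "down"))
}

#' Overlap report between two DEG sets
#'
#' @param a,b DE tables from [run_de()] (or any table with `gene_id` and
#'   `deg_call`).
#' @return Tibble: `n_a`, `n_b`, `n_both`, `n_only_a`, `n_only_b`.
#' @export
deg_overlap <- function(a, b) {
  ga <- a$gene_id[a$deg_call]; gb <- b$gene_id[b$deg_call]
  tibble::tibble(n_a = length(ga), n_b = length(gb),
                 n_both = length(intersect(ga, gb)),
                 n_only_a = length(setdiff(ga, gb)),
                 n_only_b = length(setdiff(gb, ga)))
}

#' Correlation matrix of cell-type proportion estimates
#'
#' Diagnostic behind the choice of covariates for the aware model: proportion
#' estimates live on a simplex, so including all of them in one model would
#' be collinear. This reports their pairwise Pearson correlations so users
#' can verify that the chosen pair (here neurons and oligodendrocytes) is
#' weakly correlated with each other but tracks the excluded types.
#'
#' @param proportions Tibble with `sample_id` plus one column per cell type.
#' @return Correlation matrix over the cell-type columns.
#' @export
proportion_correlations <- function(proportions) {
  num <- dplyr::select(proportions, dplyr::where(is.numeric))
  stats::cor(as.matrix(num))
}
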