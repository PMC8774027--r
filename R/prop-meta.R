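#' Per-study effect of disease status on a cell-type proportion
#'
#' Within each study, fits an ordinary least-squares model of the proportion
#' on Status plus whichever of Gender, Age, and Braak stage are available
#' (columns that are entirely missing or constant within the study are
#' dropped silently and recorded), and computes Hedges g — the small-sample
#' corrected standardized mean difference between cases and controls — with
#' its sampling variance
#' `var_g = (n1+n2)/(n1 n2) + g^2 / (2 (n1+n2))`.
#' Studies with fewer than 2 samples in either group are excluded from the
#' effect-size computation with a warning.
#'
#' @param props Numeric vector: one cell type's proportion per sample.
#' @param meta Metadata tibble (`sample_id`, `study_id`, `status`, optional
#'   `gender`, `age`, `braak`), aligned with `props`.
#' @return Tibble: `study_id`, `n_control`, `n_case`, `beta_status`,
#'   `p_lm` (two-sided OLS p for Status), `g`, `var_g`, `covariates`
#'   (comma string of covariates used).
#' @export
per_study_effect <- function(props, meta) {
  meta <- tibble::as_tibble(meta)
  if (length(props) != nrow(meta)) {
    rlang::abort("`props` and `meta` must align sample-wise.")
  }
  meta$.prop <- props
  out <- lapply(split(meta, meta$study_id), function(d) {
    n1 <- sum(d$status == "case"); n2 <- sum(d$status == "control")
    covs <- intersect(c("gender", "age", "braak"), names(d))
    usable <- covs[vapply(covs, function(cv) {
      v <- d[[cv]]
      !all(is.na(v)) && length(unique(v[!is.na(v)])) > 1 && !anyNA(v)
    }, logical(1))]
    form <- stats::reformulate(c("status", usable), response = ".prop")
    fit <- stats::lm(form, data = dplyr::mutate(
      d, status = factor(.data$status, levels = c("control", "case"))))
    co <- summary(fit)$coefficients
    eff <- if (n1 >= 2 && n2 >= 2) {
      hedges_g(d$.prop[d$status == "case"], d$.prop[d$status == "control"])
    } else {
      rlang::warn(sprintf(
        "Study '%s' has a group with < 2 samples; excluded from effect sizes.",
        d$study_id[1]))
      list(g = NA_real_, var_g = NA_real_)
    }
    tibble::tibble(
      study_id = d$study_id[1], n_control = n2, n_case = n1,
      beta_status = co["statuscase", "Estimate"],
      p_lm = co["statuscase", "Pr(>|t|)"],
      g = eff$g, var_g = eff$var_g,
      covariates = paste(usable, collapse = ","))
  })
  dplyr::bind_rows(out)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments estimate of the between-study variance tau^2 from
#' Cochran's Q, inverse-variance pooling with weights `1/(var_g + tau2)`,
#' and a two-sided normal test of the pooled standardized mean difference.
#'
#' @param g,var_g Per-study Hedges g values and sampling variances (`NA`
#'   pairs are dropped).
#' @return One-row tibble: `smd`, `se`, `tau2`, `q`, `z`, `p`, `k_studies`.
#' @export
random_effects_pool <- function(g, var_g) {
  keep <- !is.na(g) & !is.na(var_g)
  g <- g[keep]; var_g <- var_g[keep]
  if (!length(g)) rlang::abort("No usable study effects to pool.")
  if (any(var_g <= 0)) rlang::abort("All `var_g` must be > 0.")
  k <- length(g)
  w <- 1 / var_g
  g_fe <- sum(w * g) / sum(w)
  q <- sum(w * (g - g_fe)^2)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (var_g + tau2)
  smd <- sum(ws * g) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- smd / se
  tibble::tibble(smd = smd, se = se, tau2 = tau2, q = q, z = z,
                 p = 2 * stats::pnorm(-abs(z)), k_studies = k)
}

#' Meta-analysis of cell-proportion shifts across studies
#'
#' For every cell type: per-study covariate-adjusted linear models and
#' Hedges g via [per_study_effect()], then DerSimonian-Laird pooling via
#' [random_effects_pool()]; Benjamini-Hochberg correction is applied across
#' the cell types of the run.
#'
#' @param proportions Tibble: `sample_id` plus one numeric column per cell
#'   type (e.g. from [deconvolve_studies()]).
#' @param meta Metadata tibble covering the same samples.
#' @return Object of class `cyto_prop_meta`: list with `pooled` (tibble:
#'   `celltype`, `smd`, `se`, `tau2`, `q`, `z`, `p`, `p_adj`, `k_studies`)
#'   and `per_study` (long tibble of per-study effects).
#' @export
prop_meta <- function(proportions, meta) {
  proportions <- tibble::as_tibble(proportions)
  meta <- tibble::as_tibble(meta)
  if (!all(proportions$sample_id %in% meta$sample_id)) {
    rlang::abort("`meta` must cover every sample in `proportions`.")
  }
  meta <- meta[match(proportions$sample_id, meta$sample_id), ]
  types <- setdiff(names(dplyr::select(proportions, dplyr::where(is.numeric))),
                   "sample_id")
  per_study <- purrr::map_dfr(types, function(t) {
    dplyr::mutate(per_study_effect(proportions[[t]], meta), celltype = t,
                  .before = 1)
  })
  pooled <- purrr::map_dfr(types, function(t) {
    d <- dplyr::filter(per_study, .data$celltype == t)
    dplyr::mutate(random_effects_pool(d$g, d$var_g), celltype = t, .before = 1)
  })
  pooled$p_adj <- bh_adjust(pooled$p)
  structure(list(pooled = pooled, per_study = per_study),
            class = "cyto_prop_meta")
}

#' @export
print.cyto_prop_meta <- function(x, ...) {
  cat("Cell-proportion random-effects meta-analysis (DerSimonian-Laird)\n")
  print(x$pooled, ...)
  invisible(x)
}
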