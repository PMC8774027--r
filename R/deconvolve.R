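#' Realize a per-study marker panel
#'
#' For each cell type, takes the first `k` panel genes (by panel rank) that
#' are measured on the study's platform. If fewer than `k` survive, all
#' present genes are kept and a warning is issued; a cell type with no
#' present marker is an error.
#'
#' @param panel Named list: cell type -> ordered character vector of marker
#'   genes (most trusted first). No gene may belong to two types.
#' @param study_genes Character vector of genes measured in the study.
#' @param k Markers to keep per cell type.
#' @return Named list: cell type -> realized marker vector.
#' @export
select_markers <- function(panel, study_genes, k = 20) {
  if (!length(panel)) rlang::abort("`panel` is empty.")
  all_genes <- unlist(panel, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    rlang::abort("A gene is assigned to more than one cell type in `panel`.")
  }
  out <- lapply(names(panel), function(t) {
    present <- panel[[t]][panel[[t]] %in% study_genes]
    if (!length(present)) {
      rlang::abort(sprintf("Cell type '%s' has no marker on this platform.", t))
    }
    if (length(present) < k) {
      rlang::warn(sprintf(
        "Cell type '%s': only %d of %d requested markers present; keeping all.",
        t, length(present), k))
      present
    } else present[seq_len(k)]
  })
  stats::setNames(out, names(panel))
}

# Lawson-Hanson active-set NNLS on the normal equations. AtA/Atb are
# precomputed because the same design is solved against many right-hand
# sides inside the alternating loop; with a handful of unknowns each solve
# is a few tiny linear systems. Agreement with pracma::lsqnonneg is covered
# by tests.
nnls_normal <- function(AtA, Atb, tol = 1e-10) {
  k <- length(Atb)
  x <- numeric(k)
  passive <- rep(FALSE, k)
  w <- Atb
  for (outer in seq_len(30 * k)) {
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(k)
      z[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P[x[P] <= tol]] <- FALSE
      x[!passive] <- 0
    }
    w <- Atb - AtA %*% x
  }
  x
}

#' Estimate cell-type proportions by alternating non-negative least squares
#'
#' Marker-guided, reference-light deconvolution. Marker expression is
#' un-logged to the linear scale; per-type marker profiles are initialized
#' near-diagonally (each marker's own-type entry at its mean expression,
#' cross-type entries at a weak uniform background); then the algorithm
#' alternates between (a) per-sample non-negative least squares of the
#' marker vector on the current profiles followed by sum-normalization onto
#' the simplex, and (b) per-marker non-negative least squares of the gene's
#' expression on the current proportions, until the largest absolute
#' proportion change falls below `tol` or `max_iter` is reached.
#'
#' Markers span orders of magnitude in absolute expression, so the fit is
#' row-conditioned by default: each marker's values are divided by the
#' marker's mean expression, giving every marker comparable leverage in the
#' least-squares objectives. With `row_scale = FALSE` the fit runs on raw
#' linear-scale values, and rescaling one sample's markers by any constant
#' then leaves that sample's proportions exactly unchanged (sum
#' normalization absorbs it); with conditioning on, the guarantee is exact
#' for fixed weights and holds up to the O(1/n) dependence of the row means
#' on any single sample.
#'
#' @param expr Genes x samples log2 matrix.
#' @param panel Realized marker panel (named list: type -> genes), e.g. from
#'   [select_markers()]. All panel genes must be rows of `expr`.
#' The profile update is shrunk toward the marker-structured initialization
#' with an L2 penalty of weight `profile_ridge * n_samples`: per-study
#' cohorts are small (often 10-25 samples) while each marker contributes a
#' full per-type profile row, and an unpenalized update drifts away from
#' the marker structure that identifies the decomposition. Set
#' `profile_ridge = 0` for the unpenalized alternation.
#'
#' @param max_iter,tol Convergence controls.
#' @param row_scale Condition the fit by per-marker mean expression.
#' @param profile_ridge Shrinkage weight (per sample) of the profile update
#'   toward its initialization.
#' @param profiles Optional fixed marker x cell-type linear-scale signature
#'   matrix: skips the alternating profile update and performs a single
#'   per-sample NNLS against these signatures (reference-based mode). In
#'   this mode, with `row_scale = FALSE`, rescaling one sample's markers by
#'   a constant leaves that sample's proportions exactly unchanged.
#' @return Tibble `sample_id` plus one proportion column per cell type, rows
#'   on the simplex; attributes `converged`, `iterations`, `max_delta`, and
#'   `profiles` (final marker x type matrix, linear scale).
#' @export
estimate_proportions <- function(expr, panel, max_iter = 100, tol = 1e-6,
                                 row_scale = TRUE, profile_ridge = 2,
                                 profiles = NULL) {
  check_named_matrix(expr, "expr")
  if (length(panel) < 2) rlang::abort("Need >= 2 cell types.")
  if (ncol(expr) < 2) rlang::abort("Need >= 2 samples.")
  if (any(!lengths(panel))) rlang::abort("Every cell type needs >= 1 marker.")
  markers <- unlist(panel, use.names = FALSE)
  missing <- setdiff(markers, rownames(expr))
  if (length(missing)) {
    rlang::abort(sprintf("Panel genes absent from `expr`: %s",
                         paste(utils::head(missing, 5), collapse = ", ")))
  }
  types <- names(panel)
  E <- 2^expr[markers, , drop = FALSE]          # markers x samples, linear
  if (any(rowSums(E) == 0)) rlang::abort("All-zero marker row in expression.")
  w <- if (row_scale) rowMeans(E) else rep(1, nrow(E))
  E <- E / w
  n <- ncol(E); k <- length(types)

  # near-diagonal init: own-type entry = marker's mean expression,
  # cross-type entries = 20% of the global marker mean -- the typical
  # off-type background of a marker with >= 4-fold own-type separation
  P <- matrix(0.2 * mean(E), nrow = length(markers), ncol = k,
              dimnames = list(markers, types))
  own <- rep(types, lengths(panel))
  P[cbind(markers, own)] <- rowMeans(E)

  # batch NNLS against a shared design: unconstrained solve first, active-set
  # refinement only for right-hand sides that go negative
  batch_nnls <- function(AtA, AtB) {
    AtA <- AtA + diag(1e-10 * mean(diag(AtA)) + 1e-300, nrow(AtA))
    Z <- solve(AtA, AtB)
    bad <- which(apply(Z < -1e-12, 2, any))
    for (j in bad) Z[, j] <- nnls_normal(AtA, AtB[, j])
    Z[Z < 0] <- 0
    Z
  }

  if (!is.null(profiles)) {
    P <- as.matrix(profiles)[markers, types, drop = FALSE] / w
    Z <- batch_nnls(crossprod(P), crossprod(P, E))
    cs <- colSums(Z)
    Z[, cs == 0] <- 1 / k
    W <- t(Z) / ifelse(cs == 0, 1, cs)
    dimnames(W) <- list(colnames(E), types)
    out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(E)),
                            tibble::as_tibble(W))
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 0L
    attr(out, "max_delta") <- 0
    attr(out, "profiles") <- P * w
    return(out)
  }

  P0 <- P
  W <- matrix(1 / k, nrow = n, ncol = k, dimnames = list(colnames(E), types))
  converged <- FALSE; it <- 0; delta <- Inf
  ridge <- profile_ridge * n
  while (it < max_iter) {
    it <- it + 1
    # proportion step: per-sample NNLS on current profiles, then simplex
    Z <- batch_nnls(crossprod(P), crossprod(P, E))           # k x n
    cs <- colSums(Z)
    Z[, cs == 0] <- 1 / k
    W_new <- t(Z) / ifelse(cs == 0, 1, cs)
    dimnames(W_new) <- dimnames(W)
    # profile step: per-marker NNLS on current proportions, shrunk toward
    # the marker-structured initialization (see Details)
    P <- t(batch_nnls(crossprod(W_new) + diag(ridge, k),
                      crossprod(W_new, t(E)) + ridge * t(P0)))
    dimnames(P) <- list(markers, types)
    delta <- max(abs(W_new - W))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    rlang::warn(sprintf(
      "Deconvolution did not converge in %d iterations (max delta %.2e).",
      max_iter, delta))
  }
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(E)),
                          tibble::as_tibble(W))
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  attr(out, "max_delta") <- delta
  attr(out, "profiles") <- P * w   # back to the linear scale
  out
}

#' Deconvolve each study separately
#'
#' Realizes the panel against each study's measured genes (rows of `expr`
#' that are non-missing for the study's samples) with [select_markers()],
#' then runs [estimate_proportions()] per study and row-binds the results —
#' respecting platform differences between studies.
#'
#' @param expr Genes x samples log2 matrix (may contain `NA` for genes a
#'   study does not probe).
#' @param meta Metadata tibble with `sample_id` and `study_id`.
#' @param panel Ranked master marker panel (named list).
#' @param k Markers per type per study.
#' @param ... Passed to [estimate_proportions()].
#' @return Tibble `sample_id`, `study_id`, one column per cell type.
#' @export
deconvolve_studies <- function(expr, meta, panel, k = 20, ...) {
  meta <- tibble::as_tibble(meta)
  out <- lapply(split(meta$sample_id, meta$study_id), function(ids) {
    sub <- expr[, ids, drop = FALSE]
    measured <- rownames(sub)[stats::complete.cases(sub)]
    realized <- select_markers(panel, measured, k = k)
    estimate_proportions(sub[measured, , drop = FALSE], realized, ...)
  })
  dplyr::bind_rows(out, .id = "study_id") |>
    dplyr::relocate("sample_id") |>
    dplyr::arrange(match(.data$sample_id, meta$sample_id))
}

#' Compare two proportion estimates study by study
#'
#' Pearson correlation within each study between two per-sample estimates of
#' the same quantity (e.g. general-neuron vs dopaminergic-neuron fractions),
#' plus their mean and SD across studies. Studies where either vector has
#' zero variance are excluded with a warning.
#'
#' @param p1,p2 Numeric vectors over the same samples.
#' @param study Study label per sample.
#' @return Tibble of class `cyto_cmp`: `study_id`, `r`, with attributes
#'   `mean_r`, `sd_r`.
#' @export
compare_estimates <- function(p1, p2, study) {
  if (length(p1) != length(p2) || length(p1) != length(study)) {
    rlang::abort("`p1`, `p2`, `study` must have equal length.")
  }
  per <- lapply(split(seq_along(p1), study), function(idx) {
    if (stats::sd(p1[idx]) == 0 || stats::sd(p2[idx]) == 0) return(NA_real_)
    stats::cor(p1[idx], p2[idx])
  })
  out <- tibble::tibble(study_id = names(per),
                        r = unname(unlist(per)))
  if (anyNA(out$r)) {
    rlang::warn(sprintf("Zero-variance studies excluded: %s",
                        paste(out$study_id[is.na(out$r)], collapse = ", ")))
  }
  attr(out, "mean_r") <- mean(out$r, na.rm = TRUE)
  attr(out, "sd_r") <- stats::sd(out$r, na.rm = TRUE)
  class(out) <- c("cyto_cmp", class(out))
  out
}
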