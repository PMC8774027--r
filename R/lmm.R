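# Exact REML machinery for the random-intercept-per-study model
#
#   y = X beta + Z u + e,  u ~ N(0, sigma_u^2 I_k),  e ~ N(0, sigma_e^2 I_n)
#
# With a single grouping factor, V(lambda) = I + lambda Z Z' is block
# diagonal (lambda = sigma_u^2 / sigma_e^2) and every REML quantity reduces
# to per-study sufficient statistics, so the 1-D profiled likelihood can be
# optimized in microseconds per gene. Satterthwaite degrees of freedom are
# computed analytically from blockwise trace algebra: every block matrix in
# sight has the form a*I + b*11', a family closed under multiplication.

# --- (a, b) block algebra -------------------------------------------------
# A block matrix a*I + b*11' is stored as list(a =, b =) with one entry per
# study, so products vectorize across studies.
bk_mult <- function(x, y, nj) {
  list(a = x$a * y$a, b = x$a * y$b + x$b * y$a + x$b * y$b * nj)
}
bk_prod <- function(factors, nj) {
  Reduce(function(x, y) bk_mult(x, y, nj), factors)
}
bk_trace <- function(x, nj) sum(nj * (x$a + x$b))

# Per-study design statistics shared by every gene with the same
# missingness pattern. S_mat holds the per-study column sums of X as
# columns, so  sum_j c_j s_j s_j' = S_mat %*% (c * t(S_mat))  vectorizes.
lmm_design_stats <- function(X, study) {
  study <- as.character(study)
  idx <- split(seq_len(nrow(X)), study)
  idx <- idx[lengths(idx) > 0]
  XtX <- lapply(idx, function(i) crossprod(X[i, , drop = FALSE]))
  S_mat <- vapply(idx, function(i) colSums(X[i, , drop = FALSE]),
                  numeric(ncol(X)))
  list(
    idx = idx, group = factor(study, levels = names(idx)),
    n = nrow(X), p = ncol(X), k = length(idx),
    nj = vapply(idx, length, integer(1)),
    XtX = XtX, XtX_sum = Reduce(`+`, XtX),
    XtX_flat = vapply(XtX, as.vector, numeric(ncol(X)^2)),  # p^2 x k
    S_mat = S_mat
  )
}

# Per-study response statistics, vectorized over studies.
lmm_y_stats <- function(X, y, st) {
  list(Xty = t(rowsum(X * y, st$group)),            # p x k
       tj = as.vector(rowsum(y, st$group)),
       ytyj = as.vector(rowsum(y^2, st$group)))
}

# GLS pieces at a given lambda.
lmm_gls <- function(lambda, st, ys) {
  cj <- lambda / (1 + lambda * st$nj)
  A <- st$XtX_sum - st$S_mat %*% (cj * t(st$S_mat))
  b <- rowSums(ys$Xty) - st$S_mat %*% (cj * ys$tj)
  q <- sum(ys$ytyj) - sum(cj * ys$tj^2)
  beta <- solve(A, b)
  rss <- max(q - sum(b * beta), .Machine$double.eps)
  list(A = A, beta = drop(beta), rss = rss,
       logdetV = sum(log1p(lambda * st$nj)))
}

lmm_reml_crit <- function(lambda, st, ys) {
  g <- lmm_gls(lambda, st, ys)
  g$logdetV + determinant(g$A, logarithm = TRUE)$modulus[1] +
    (st$n - st$p) * log(g$rss)
}

# c' (X' Sigma^{-1} X)^{-1} c as a function of (sigma_u^2, sigma_e^2).
lmm_phi <- function(s2u, s2e, st, c_idx) {
  dj <- s2u / (s2e + st$nj * s2u)
  A <- (st$XtX_sum - st$S_mat %*% (dj * t(st$S_mat))) / s2e
  solve(A)[c_idx, c_idx]
}

# REML information-based covariance of (sigma_u^2, sigma_e^2) and the
# Satterthwaite df for the c_idx-th coefficient.
lmm_satterthwaite <- function(s2u, s2e, st, c_idx) {
  nj <- st$nj
  S <- list(a = rep(1 / s2e, st$k),
            b = -s2u / (s2e * (s2e + nj * s2u)))
  ZZ <- list(a = rep(0, st$k), b = rep(1, st$k))
  ID <- list(a = rep(1, st$k), b = rep(0, st$k))
  # X' (block-diagonal a*I + b*11') X from per-study sufficient statistics
  xbx <- function(pr) {
    matrix(st$XtX_flat %*% pr$a, st$p, st$p) +
      st$S_mat %*% (pr$b * t(st$S_mat))
  }
  B <- solve(xbx(S))  # (X' Sigma^{-1} X)^{-1}
  tr_PP <- function(Ai, Ci) {
    T1 <- bk_trace(bk_prod(list(S, Ai, S, Ci), nj), nj)
    T2 <- sum(xbx(bk_prod(list(S, Ci, S, Ai, S), nj)) * B)
    T3 <- sum(xbx(bk_prod(list(S, Ai, S, Ci, S), nj)) * B)
    HA <- xbx(bk_prod(list(S, Ai, S), nj))
    HC <- xbx(bk_prod(list(S, Ci, S), nj))
    T4 <- sum(diag(B %*% HA %*% B %*% HC))
    T1 - T2 - T3 + T4
  }
  SIG <- list(ZZ, ID)
  info <- matrix(NA_real_, 2, 2)
  info[1, 1] <- 0.5 * tr_PP(SIG[[1]], SIG[[1]])
  info[1, 2] <- info[2, 1] <- 0.5 * tr_PP(SIG[[1]], SIG[[2]])
  info[2, 2] <- 0.5 * tr_PP(SIG[[2]], SIG[[2]])
  vcov_theta <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vcov_theta)) return(NULL)
  h <- 1e-5 * s2e
  gphi <- c(
    (lmm_phi(s2u + h, s2e, st, c_idx) - lmm_phi(s2u - h, s2e, st, c_idx)) / (2 * h),
    (lmm_phi(s2u, s2e + h, st, c_idx) - lmm_phi(s2u, s2e - h, st, c_idx)) / (2 * h)
  )
  phi <- lmm_phi(s2u, s2e, st, c_idx)
  denom <- drop(t(gphi) %*% vcov_theta %*% gphi)
  if (!is.finite(denom) || denom <= 0) return(NULL)
  df <- 2 * phi^2 / denom
  if (!is.finite(df) || df <= 0) return(NULL)
  df
}

# Fit one response by exact 1-D REML; returns the Status inference.
# `st` may be passed precomputed (run_de caches it per missingness pattern).
lmm_reml_engine <- function(X, y, study, c_name, st = NULL) {
  if (is.null(st)) st <- lmm_design_stats(X, study)
  ys <- lmm_y_stats(X, y, st)
  crit <- function(loglam) lmm_reml_crit(exp(loglam), st, ys)
  opt <- stats::optimize(crit, interval = c(-25, 15), tol = 1e-7)
  crit0 <- lmm_reml_crit(0, st, ys)
  lambda <- if (crit0 <= opt$objective) 0 else exp(opt$minimum)
  g <- lmm_gls(lambda, st, ys)
  s2e <- g$rss / (st$n - st$p)
  s2u <- lambda * s2e
  Ainv <- solve(g$A)
  c_idx <- match(c_name, colnames(X))
  beta <- unname(g$beta[c_idx])
  se <- unname(sqrt(s2e * Ainv[c_idx, c_idx]))
  df <- lmm_satterthwaite(s2u, s2e, st, c_idx)
  if (is.null(df)) {
    p <- 2 * stats::pnorm(-abs(beta / se))
    df_method <- "wald-z"; df <- Inf
  } else {
    p <- 2 * stats::pt(-abs(beta / se), df)
    df_method <- "satterthwaite"
  }
  list(beta = beta, se = se, df = df, p = p, df_method = df_method,
       sigma2_study = s2u, sigma2_resid = s2e, n_studies = st$k)
}

lmm_build_design <- function(meta, proportions, mode) {
  d <- data.frame(status = factor(meta$status, levels = c("control", "case")),
                  gender = factor(meta$gender))
  form <- ~ status + gender
  if (mode == "aware") {
    if (is.null(proportions) || !all(c("neu", "odc") %in% colnames(proportions))) {
      rlang::abort("Aware mode needs `proportions` with `neu` and `odc` columns.")
    }
    d$neu <- proportions$neu[match(meta$sample_id, proportions$sample_id)]
    d$odc <- proportions$odc[match(meta$sample_id, proportions$sample_id)]
    if (anyNA(d$neu) || anyNA(d$odc)) {
      rlang::abort("`proportions` does not cover every sample in `meta`.")
    }
    form <- ~ status + gender + neu + odc
  }
  X <- stats::model.matrix(form, d)
  # covariates constant across samples carry no information and are
  # collinear with the intercept: drop them, so e.g. aware mode with
  # constant proportions reduces to the unaware model
  const <- apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1)
  if (any(const)) X <- X[, c(TRUE, !const), drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    rlang::abort(sprintf("Singular fixed-effect design; collinear column(s): %s",
                         paste(bad, collapse = ", ")))
  }
  X
}

#' Fit the per-gene random-intercept mixed model
#'
#' Fits `expression ~ Status + Gender (+ NEU + ODC) + (1 | Study)` by
#' restricted maximum likelihood and tests the Status coefficient with
#' Satterthwaite-approximated degrees of freedom. The "aware" mode adds the
#' neuron and oligodendrocyte proportion estimates as fixed effects — the
#' correction for cell-composition shifts; only those two types enter, to
#' avoid collinear predictors among proportions that sum to one.
#'
#' The default engine is an exact blockwise REML solver specialized to the
#' single-random-intercept structure (1-D profiled likelihood, analytic
#' Satterthwaite via trace algebra); `engine = "lmer"` delegates to
#' [lmerTest::lmer()] and gives the same answers, orders of magnitude
#' slower. When the Satterthwaite approximation is unavailable (boundary
#' fits with a degenerate information matrix) the test falls back to a
#' Wald z and flags it in `df_method`.
#'
#' @param y Per-sample expression (log2), `NA` allowed; samples with
#'   missing `y` are excluded.
#' @param meta Metadata tibble: `sample_id`, `study_id`, `status`
#'   ("control"/"case"), `gender`.
#' @param proportions Tibble with `sample_id`, `neu`, `odc` (aware mode).
#' @param mode `"unaware"` or `"aware"`.
#' @param engine `"reml"` (blockwise, default) or `"lmer"` (lmerTest).
#' @return One-row tibble: `beta_status`, `se`, `df`, `p`, `df_method`,
#'   `n_studies`, `sigma2_study`, `sigma2_resid`.
#' @export
fit_gene_lmm <- function(y, meta, proportions = NULL,
                         mode = c("unaware", "aware"),
                         engine = c("reml", "lmer")) {
  mode <- match.arg(mode); engine <- match.arg(engine)
  meta <- tibble::as_tibble(meta)
  keep <- !is.na(y)
  if (length(unique(meta$study_id[keep])) < 2) {
    rlang::abort("Gene observed in fewer than 2 studies.",
                 class = "cyto_single_study")
  }
  meta <- meta[keep, ]; y <- y[keep]
  X <- lmm_build_design(meta, proportions, mode)
  if (engine == "reml") {
    fit <- lmm_reml_engine(X, y, meta$study_id, "statuscase")
  } else {
    d <- as.data.frame(X[, -1, drop = FALSE])
    d$y <- y; d$study <- meta$study_id
    form <- stats::reformulate(c(colnames(X)[-1], "(1 | study)"), response = "y")
    m <- lmerTest::lmer(form, data = d, REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
    co <- summary(m)$coefficients["statuscase", ]
    vc <- as.data.frame(lme4::VarCorr(m))
    fit <- list(beta = co[["Estimate"]], se = co[["Std. Error"]],
                df = co[["df"]], p = co[["Pr(>|t|)"]],
                df_method = "satterthwaite",
                sigma2_study = vc$vcov[vc$grp == "study"],
                sigma2_resid = vc$vcov[vc$grp == "Residual"],
                n_studies = length(unique(meta$study_id)))
  }
  tibble::tibble(beta_status = fit$beta, se = fit$se, df = fit$df, p = fit$p,
                 df_method = fit$df_method, n_studies = fit$n_studies,
                 sigma2_study = fit$sigma2_study,
                 sigma2_resid = fit$sigma2_resid)
}
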