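#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment. Order of the input is preserved;
#' monotonicity is enforced as in the standard step-up procedure.
#'
#' @param p Numeric vector of p-values, all in \[0, 1\]. `NA` is propagated.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) rlang::abort("`p` must be numeric.")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    rlang::abort(sprintf("p-values outside [0, 1] at positions: %s",
                         paste(which(bad), collapse = ", ")))
  }
  stats::p.adjust(p, method = "BH")
}

# Dirichlet draws, rows on the simplex. alpha recycled per row.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Stop unless x is a numeric matrix with row and column names.
check_named_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    rlang::abort(sprintf("`%s` must be a numeric matrix.", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    rlang::abort(sprintf("`%s` must have row and column names.", what))
  }
  invisible(x)
}

# Hedges g with small-sample correction J, plus its sampling variance.
hedges_g <- function(x_case, x_control) {
  n1 <- length(x_case); n2 <- length(x_control)
  s2p <- ((n1 - 1) * stats::var(x_case) + (n2 - 1) * stats::var(x_control)) /
    (n1 + n2 - 2)
  if (s2p <= 0) rlang::abort("Zero pooled variance: standardized difference undefined.")
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- j * (mean(x_case) - mean(x_control)) / sqrt(s2p)
  list(g = g, var_g = (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
}

# Nearest-rank percentile: value at ceiling(pct/100 * n) of the sorted vector.
nearest_rank_percentile <- function(x, pct) {
  xs <- sort(x)
  xs[max(1L, ceiling(pct / 100 * length(xs)))]
}
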