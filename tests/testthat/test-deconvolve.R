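panel6 <- function(n_per = 6) {
  types <- c("ast", "end", "mic", "neu", "odc", "opc")
  stats::setNames(lapply(seq_along(types), function(i) {
    sprintf("%s_m%02d", types[i], seq_len(n_per))
  }), types)
}

test_that("marker realization keeps panel rank order and skips absent genes", {
  panel <- panel6(6)
  all_genes <- unlist(panel)
  expect_equal(select_markers(panel, all_genes, k = 4),
               lapply(panel, head, 4))
  # rank-3 marker missing -> ranks 1,2,4,5 kept at k = 4
  platform <- setdiff(all_genes, "neu_m03")
  out <- select_markers(panel, platform, k = 4)
  expect_equal(out$neu, c("neu_m01", "neu_m02", "neu_m04", "neu_m05"))
  # fewer than k present -> all kept with a warning
  w <- testthat::capture_warnings(
    out2 <- select_markers(panel, all_genes[c(1:3, 7:40)], k = 6))
  expect_true(any(grepl("keeping all", w)))
  expect_equal(out2$ast, panel$ast[1:3])
  expect_error(
    suppressWarnings(select_markers(panel, setdiff(all_genes, panel$mic))),
    "mic")
  dup <- panel; dup$end[1] <- dup$ast[1]
  expect_error(select_markers(dup, all_genes), "more than one")
})

test_that("marker realization matches an independent filter-then-truncate oracle", {
  panel <- panel6(20)
  withr::with_seed(21, {
    platform <- sample(unlist(panel), round(0.7 * 120))
  })
  out <- select_markers(panel, platform, k = 10)
  oracle <- lapply(panel, function(gs) utils::head(gs[gs %in% platform], 10))
  expect_equal(suppressWarnings(select_markers(panel, platform, k = 10)),
               oracle)
  expect_equal(out, oracle)
})

test_that("the fast NNLS solver agrees with pracma on random problems", {
  skip_if_not_installed("pracma")
  withr::with_seed(31, {
    for (i in 1:25) {
      A <- matrix(stats::runif(40 * 6), 40, 6)
      b <- stats::runif(40)
      x_ref <- pracma::lsqnonneg(A, b)$x
      x <- cytometa:::nnls_normal(crossprod(A), crossprod(A, b)[, 1])
      expect_equal(x, x_ref, tolerance = 1e-6)
    }
  })
})

test_that("pure cell-type signatures deconvolve to near one-hot proportions", {
  cfg <- mixture_cfg(seed = 3, noise_sd = 0)
  ref <- simulate_reference(cfg)
  onehot <- diag(6)[rep(1:6, each = 3), ]  # 3 pure samples per type
  rownames(onehot) <- sprintf("pure%02d", 1:18)
  expr <- mix_bulk(onehot, ref$reference)
  est <- estimate_proportions(expr, ref$marker_map)
  em <- as.matrix(est[, -1])
  expect_true(all(em[cbind(1:18, rep(1:6, each = 3))] >= 0.99))
})

test_that("mixed proportions are recovered within the accuracy contract", {
  cfg <- mixture_cfg(seed = 17, noise_sd = 0.1)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk(cfg, ref)
  est <- estimate_proportions(sim$expr, ref$marker_map)
  truth <- as.matrix(sim$truth$true_proportions[, -1])
  em <- as.matrix(est[, -1])[match(sim$truth$true_proportions$sample_id,
                                   est$sample_id), ]
  expect_lte(mean(abs(em - truth)), 0.05)
  # simplex contract on any output
  expect_lt(max(abs(rowSums(as.matrix(est[, -1])) - 1)), 1e-6)
  expect_true(all(as.matrix(est[, -1]) >= 0))
})

test_that("estimates ignore sample order and marker order within a type", {
  cfg <- mixture_cfg(seed = 19, n = 12)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk(cfg, ref)
  est <- estimate_proportions(sim$expr, ref$marker_map)
  perm <- withr::with_seed(1, sample(ncol(sim$expr)))
  est_p <- estimate_proportions(sim$expr[, perm], ref$marker_map)
  expect_equal(as.data.frame(est_p[match(est$sample_id, est_p$sample_id), ]),
               as.data.frame(est), tolerance = 1e-9)
  shuffled <- lapply(ref$marker_map, function(g) withr::with_seed(2, sample(g)))
  est_m <- estimate_proportions(sim$expr, shuffled)
  expect_equal(as.matrix(est_m[, -1]), as.matrix(est[, -1]), tolerance = 1e-9)
})

test_that("per-sample rescaling is absorbed exactly against fixed signatures", {
  cfg <- mixture_cfg(seed = 23, n = 10)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk(cfg, ref)
  sig <- t(ref$reference[, unlist(ref$marker_map)])
  base <- estimate_proportions(sim$expr, ref$marker_map, row_scale = FALSE,
                               profiles = sig)
  scaled <- sim$expr
  scaled[, 4] <- scaled[, 4] + log2(7)  # 7x on the linear scale
  redo <- estimate_proportions(scaled, ref$marker_map, row_scale = FALSE,
                               profiles = sig)
  expect_equal(as.matrix(redo[, -1]), as.matrix(base[, -1]), tolerance = 1e-9)
})

test_that("estimated and true proportions are rank-concordant across replicates", {
  med_cors <- vapply(1:5, function(s) {
    sim <- small_sim(s * 100 + 1)
    props <- suppressWarnings(deconvolve_studies(
      sim$expr, sim$meta, sim$truth$marker_map, k = 8))
    tp <- sim$truth$true_proportions
    m <- match(tp$sample_id, props$sample_id)
    median(vapply(c("ast", "end", "mic", "neu", "odc", "opc"), function(t) {
      stats::cor(props[[t]][m], tp[[t]], method = "spearman")
    }, numeric(1)))
  }, numeric(1))
  expect_gte(median(med_cors), 0.8)
})

test_that("per-study correlation aggregation matches hand-computed values", {
  p1 <- c(0.1, 0.2, 0.3, 0.5, 0.4, 0.1)
  study <- rep(c("s1", "s2"), each = 3)
  idp <- compare_estimates(p1, p1, study)
  expect_equal(idp$r, c(1, 1))
  anti <- compare_estimates(p1, 1 - p1, study)
  expect_equal(anti$r, c(-1, -1))
  p2 <- c(0.2, 0.1, 0.4, 0.1, 0.5, 0.3)
  out <- compare_estimates(p1, p2, study)
  expect_equal(out$r, c(stats::cor(p1[1:3], p2[1:3]),
                        stats::cor(p1[4:6], p2[4:6])))
  expect_equal(attr(out, "mean_r"), mean(out$r))
  expect_warning(compare_estimates(c(1, 1, 1, 0.2, 0.4, 0.1), p2, study),
                 "Zero-variance")
})
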