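test_that("configuration is validated", {
  expect_error(sim_config(n_genes = 50, n_celltypes = 6,
                          n_markers_per_type = 10), "exceeds")
  expect_error(sim_config(study_sd = -1), "deviations")
  expect_error(sim_config(dirichlet_alpha_control = rep(0, 6)), "alphas")
  expect_error(sim_config(n_control = c(5, 5)), "length")
})

test_that("the same seed reproduces reference, bulk, and PPI bit-identically", {
  cfg <- small_cfg(3)
  r1 <- simulate_reference(cfg); r2 <- simulate_reference(cfg)
  expect_identical(r1, r2)
  s1 <- simulate_bulk(cfg, r1); s2 <- simulate_bulk(cfg, r2)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_ppi(60, 2, 0.08, seed = 5),
                   simulate_ppi(60, 2, 0.08, seed = 5))
})

test_that("markers separate their own type by at least marker_lfc, exhaustively", {
  cfg <- small_cfg(2, marker_lfc = 2)
  ref <- simulate_reference(cfg)
  for (t in names(ref$marker_map)) {
    for (g in ref$marker_map[[t]]) {
      own <- ref$reference[t, g]
      other_max <- max(ref$reference[setdiff(rownames(ref$reference), t), g])
      expect_gte(own / other_max, 4)  # 2^marker_lfc
    }
  }
  expect_true(all(ref$reference >= 0))
})

test_that("marker map holds n_celltypes x n_markers_per_type distinct genes", {
  cfg <- sim_config(n_genes = 500, n_celltypes = 6, n_markers_per_type = 20,
                    seed = 9)
  mm <- simulate_reference(cfg)$marker_map
  genes <- unlist(mm)
  expect_length(genes, 120)
  expect_length(unique(genes), 120)
})

test_that("one-hot proportions reproduce log2 reference rows exactly", {
  cfg <- small_cfg(4)
  ref <- simulate_reference(cfg)$reference
  onehot <- diag(nrow(ref))
  rownames(onehot) <- paste0("pure_", rownames(ref))
  bulk <- mix_bulk(onehot, ref)
  for (i in seq_len(nrow(ref))) {
    expect_equal(unname(bulk[, i]), unname(log2(ref[i, ])), tolerance = 1e-12)
  }
})

test_that("NNLS against the true reference recovers mixed proportions", {
  skip_if_not_installed("pracma")
  cfg <- mixture_cfg(seed = 13, noise_sd = 0.1)
  ref <- simulate_reference(cfg)
  sim <- simulate_bulk(cfg, ref)
  truth <- as.matrix(sim$truth$true_proportions[, -1])
  # independent oracle: plain NNLS per sample on the full true signatures
  est <- t(apply(2^sim$expr, 2, function(b) {
    x <- pracma::lsqnonneg(t(ref$reference), b)$x
    x / sum(x)
  }))
  expect_lt(mean(abs(est - truth)), 0.03)
})

test_that("ground truth echoes the configuration and stays on the simplex", {
  sim <- small_sim(6, n_true_degs = 12)
  expect_equal(nrow(sim$truth$true_degs), 12)
  expect_true(all(sim$truth$true_degs$gene_id %in% rownames(sim$expr)))
  rs <- rowSums(as.matrix(sim$truth$true_proportions[, -1]))
  expect_lt(max(abs(rs - 1)), 1e-9)
  expect_equal(nrow(sim$meta), ncol(sim$expr))
})

test_that("the generative equation inverts exactly at zero noise", {
  sim <- small_sim(8, study_sd = 0, noise_sd = 0)
  cfg <- small_cfg(8, study_sd = 0, noise_sd = 0)
  ref <- simulate_reference(cfg)
  tp <- as.matrix(sim$truth$true_proportions[, -1])
  rownames(tp) <- sim$truth$true_proportions$sample_id
  recon <- mix_bulk(tp, ref$reference)
  # add back the recorded planted effects
  case <- sim$meta$sample_id[sim$meta$status == "case"]
  for (i in seq_len(nrow(sim$truth$true_degs))) {
    g <- sim$truth$true_degs$gene_id[i]
    recon[g, case] <- recon[g, case] + sim$truth$true_degs$effect[i]
  }
  male <- sim$meta$sample_id[sim$meta$gender == "M"]
  recon[sim$truth$gender_gene_ids, male] <-
    recon[sim$truth$gender_gene_ids, male] + 2
  expect_lt(max(abs(recon - sim$expr[, rownames(tp)])), 1e-9)
})

test_that("larger planted effects increase the observed case-control gap", {
  gaps <- vapply(c(0.5, 1.5), function(eff) {
    cfg <- sim_config(n_genes = 200, n_markers_per_type = 5, n_true_degs = 40,
                      deg_effect = eff, seed = 10)
    sim <- simulate_bulk(cfg, simulate_reference(cfg))
    deg <- sim$truth$true_degs$gene_id
    case <- sim$meta$status == "case"
    mean(abs(rowMeans(sim$expr[deg, case]) - rowMeans(sim$expr[deg, !case])))
  }, numeric(1))
  expect_gt(gaps[2], gaps[1])
})

test_that("simulated PPI graphs are simple with planted hubs on top", {
  edges <- simulate_ppi(100, 3, 0.05, seed = 2)
  expect_true(all(edges$a != edges$b))
  key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  expect_false(any(duplicated(key)))
  deg <- table(c(edges$a, edges$b))
  top3 <- names(sort(deg, decreasing = TRUE))[1:3]
  expect_setequal(top3, attr(edges, "hubs"))
  # hubs attach to at least 30% of nodes
  expect_true(all(deg[attr(edges, "hubs")] >= 30))
  expect_error(simulate_ppi(10, 10, 0.1), "n_hubs")
  expect_error(simulate_ppi(10, 2, 1.5), "edge_density")
})
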