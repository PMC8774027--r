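test_that("the ranking metric is the signed log of adjusted p", {
  tab <- tibble::tibble(gene_id = c("a", "b", "c"),
                        p_adj = c(0.001, 1, 0.01),
                        beta_status = c(2, -1, -0.5))
  r <- rank_genes(tab)
  expect_equal(r$score[r$item == "a"], 3)
  expect_equal(r$score[r$item == "b"], 0)
  expect_equal(r$score[r$item == "c"], -2)
  expect_equal(r$item, c("a", "b", "c"))  # descending with id tie-break
  tab$p_adj[2] <- NA
  expect_error(rank_genes(tab), "b")
})

test_that("GMT round-trips and rejects malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc one\tA\tB\tA", "S2\td2\tC\tD"), path)
  sets <- read_gmt(path)
  expect_equal(sets$S1, c("A", "B"))
  expect_equal(sets$S2, c("C", "D"))
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(read_gmt(out)[], sets[])
  writeLines(c("S1\tdesc\tA", "bad\tonlydesc"), path)
  expect_error(read_gmt(path), "2")
  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), empty)
  expect_length(read_gmt(empty), 0)
})

test_that("ES and p match exhaustive enumeration on a 10-item list", {
  scores <- c(3.2, 2.5, 1.9, 1.2, 0.7, -0.3, -0.9, -1.6, -2.2, -3.1)
  items <- letters[1:10]
  ranks <- tibble::tibble(item = items, score = scores)
  sets <- list(top = c("a", "b", "c"), mid = c("d", "e", "f"),
               bottom = c("h", "i", "j"), spread = c("a", "e", "j"))
  res <- gsea_preranked(ranks, sets, min_size = 3, max_size = 10,
                        exhaustive = TRUE, seed = 1)
  all_combos <- utils::combn(10, 3)
  null_es <- apply(all_combos, 2, function(pos) {
    es_oracle(seq_len(10) %in% pos, scores)
  })
  for (nm in names(sets)) {
    pos <- match(sets[[nm]], items)
    es_expected <- es_oracle(seq_len(10) %in% pos, scores)
    row <- res[res$set_id == nm, ]
    expect_equal(row$es, es_expected, tolerance = 1e-12)
    same <- if (es_expected >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p_expected <- (1 + sum(abs(same) >= abs(es_expected) * (1 - 1e-9))) /
      (1 + length(same))
    expect_equal(row$p, p_expected, tolerance = 1e-12)
    expect_equal(sign(row$nes), sign(row$es))
  }
  expect_gt(res$es[res$set_id == "top"], 0)
  expect_gte(res$es[res$set_id == "top"], max(res$es))
  expect_lt(res$es[res$set_id == "bottom"], 0)
})

test_that("ES is antisymmetric and scale-invariant", {
  withr::with_seed(5, {
    scores <- sort(rnorm(40), decreasing = TRUE)
    items <- sprintf("i%02d", 1:40)
    set <- list(s = sample(items, 8))
  })
  ranks <- tibble::tibble(item = items, score = scores)
  a <- gsea_preranked(ranks, set, n_perm = 50, min_size = 3, seed = 2)
  flipped <- tibble::tibble(item = rev(items), score = rev(-scores))
  b <- gsea_preranked(flipped, set, n_perm = 50, min_size = 3, seed = 2)
  expect_equal(b$es, -a$es, tolerance = 1e-12)
  rescaled <- tibble::tibble(item = items, score = 13.7 * scores)
  c_ <- gsea_preranked(rescaled, set, n_perm = 50, min_size = 3, seed = 2)
  expect_equal(c_$es, a$es, tolerance = 1e-12)
})

test_that("our ES agrees with fgsea on a realistic ranking", {
  skip_if_not_installed("fgsea")
  withr::with_seed(6, {
    n <- 200
    stats <- sort(rnorm(n, 0, 2), decreasing = TRUE)
    names(stats) <- sprintf("G%03d", 1:n)
    sets <- lapply(1:5, function(i) sample(names(stats), 20))
    names(sets) <- paste0("S", 1:5)
  })
  ours <- gsea_preranked(stats, sets, n_perm = 10, min_size = 5, seed = 3)
  ref <- suppressWarnings(fgsea::fgsea(sets, stats, nperm = 100,
                                       gseaParam = 1))
  expect_equal(ours$es[match(ref$pathway, ours$set_id)], ref$ES,
               tolerance = 1e-6)
})

test_that("fixed seeds reproduce GSEA bit-identically and sets are size-filtered", {
  withr::with_seed(7, {
    scores <- sort(rnorm(100), decreasing = TRUE)
    items <- sprintf("i%03d", 1:100)
    sets <- list(small = items[1:3], ok = sample(items, 20),
                 missing = c(sample(items, 15), "absent_gene"))
  })
  ranks <- tibble::tibble(item = items, score = scores)
  r1 <- gsea_preranked(ranks, sets, n_perm = 200, min_size = 15, seed = 9)
  r2 <- gsea_preranked(ranks, sets, n_perm = 200, min_size = 15, seed = 9)
  expect_identical(r1, r2)
  expect_false("small" %in% r1$set_id)
  expect_equal(r1$set_size_used[r1$set_id == "missing"], 15)
  expect_warning(gsea_preranked(ranks, list(tiny = items[1:2]),
                                n_perm = 10), "size filter")
})

test_that("null GSEA p-values are close to uniform", {
  withr::with_seed(10, {
    scores <- sort(rnorm(150), decreasing = TRUE)
    items <- sprintf("i%03d", 1:150)
    sets <- lapply(1:400, function(i) sample(items, 15))
    names(sets) <- paste0("S", 1:400)
  })
  ranks <- tibble::tibble(item = items, score = scores)
  res <- gsea_preranked(ranks, sets, n_perm = 400, min_size = 10, seed = 11)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
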