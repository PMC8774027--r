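edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(a = m[, 1], b = m[, 2])
}

test_that("network merging dedupes, drops self-loops, prunes degree-1 once", {
  lists <- list(
    db1 = edge_df("a", "b", "b", "c", "c", "c"),
    db2 = edge_df("B", "A", "a", "c", "c", "d", "d", "e", "e", "c"))
  g <- merge_networks(lists)
  # A-B present in both sources, recorded once with both tags
  eid <- igraph::get_edge_ids(g, c("A", "B"))
  expect_gt(eid, 0)
  expect_equal(igraph::E(g)$sources[eid], "db1;db2")
  expect_equal(igraph::ecount(g), 6)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D", "E"))
  expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
})

test_that("degree-1 pruning is a single pass", {
  g <- merge_networks(list(src = edge_df("a", "b", "b", "c", "c", "d")))
  # path A-B-C-D: A and D leave; B-C stays although now degree 1
  expect_setequal(igraph::V(g)$name, c("B", "C"))
  expect_equal(igraph::ecount(g), 1)
  expect_error(merge_networks(list(s = edge_df("x", "x"))), "empty")
})

test_that("merging a merged graph with itself changes nothing", {
  lists <- list(db1 = edge_df("a", "b", "b", "c", "c", "a", "c", "d", "d", "a"))
  g <- merge_networks(lists)
  back <- tibble::as_tibble(igraph::as_data_frame(g)[, 1:2])
  g2 <- merge_networks(list(db1 = back))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  a1 <- igraph::as_data_frame(g)[, 1:2]; a2 <- igraph::as_data_frame(g2)[, 1:2]
  key <- function(d) sort(paste(pmin(d[, 1], d[, 2]), pmax(d[, 1], d[, 2])))
  expect_equal(key(a1), key(a2))
})

test_that("seed neighborhoods induce the right subgraphs", {
  g <- merge_networks(list(s = edge_df(
    "a", "b", "a", "c", "a", "d", "b", "c", "d", "e", "e", "f", "f", "d",
    "g", "h", "h", "a")))
  all_nodes <- igraph::V(g)$name
  expect_setequal(igraph::V(ppi_neighborhood(g, all_nodes))$name, all_nodes)
  nb <- ppi_neighborhood(g, "E")
  expect_setequal(igraph::V(nb)$name, c("E", "D", "F"))
  # induced edges include D-F even though neither is the seed
  expect_equal(igraph::ecount(nb), 3)
  expect_error(ppi_neighborhood(g, "zz"), "No seed")
  # a star from its center
  star <- igraph::graph_from_data_frame(
    data.frame(from = "HUB", to = c("L1", "L2", "L3")), directed = FALSE)
  expect_setequal(igraph::V(ppi_neighborhood(star, "HUB"))$name,
                  c("HUB", "L1", "L2", "L3"))
})

test_that("centrality has the textbook closed forms", {
  star <- igraph::graph_from_data_frame(
    data.frame(from = "C", to = paste0("L", 1:5)), directed = FALSE)
  tab <- ppi_centrality(star)
  expect_equal(tab$betweenness[tab$node == "C"], choose(5, 2))
  expect_true(all(tab$betweenness[tab$node != "C"] == 0))
  path <- igraph::graph_from_literal(x - y, y - z)
  ptab <- ppi_centrality(path)
  expect_equal(ptab$betweenness[ptab$node == "y"], 1)
})

test_that("betweenness equals the all-pairs path-counting oracle", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      n <- sample(8:25, 1)
      adj <- matrix(0, n, n)
      pairs <- which(upper.tri(adj), arr.ind = TRUE)
      on <- pairs[stats::runif(nrow(pairs)) < 0.25, , drop = FALSE]
      adj[on] <- 1; adj <- adj + t(adj)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      igraph::V(g)$name <- paste0("n", seq_len(n))
      tab <- ppi_centrality(g)
      expect_equal(tab$betweenness, betweenness_oracle(adj), tolerance = 1e-9)
    }
  })
})

test_that("central-node selection intersects the two percentile rules with ties", {
  tab <- tibble::tibble(node = paste0("n", 1:10),
                        degree = c(rep(1, 8), 9, 9),
                        betweenness = c(rep(0, 8), 50, 0))
  out <- central_nodes(tab, pct = 95)
  # n10 is top 5% by degree but low betweenness -> excluded
  expect_equal(out$node[out$is_central], "n9")
  # all-identical centralities -> everyone central (tie inclusion)
  flat <- tibble::tibble(node = paste0("n", 1:6), degree = 3, betweenness = 2)
  expect_true(all(central_nodes(flat)$is_central))
  expect_error(central_nodes(tab, pct = 101), "pct")
  # deg-encoded nodes cannot be top central
  out2 <- central_nodes(tab, deg_encoded = "n9")
  expect_true(out2$is_central[out2$node == "n9"])
  expect_false(out2$is_top_central[out2$node == "n9"])
})

test_that("planted hubs are recovered as central nodes", {
  edges <- simulate_ppi(100, 5, 0.05, seed = 8)
  g <- merge_networks(list(sim = edges))
  tab <- central_nodes(ppi_centrality(g))
  expect_true(all(toupper(attr(edges, "hubs")) %in% tab$node[tab$is_central]))
})

test_that("hypergeometric enrichment matches brute-force subset counting", {
  # universe of 10 with 3 category members; draw 4: enumerate all draws
  combos <- utils::combn(10, 4)
  in_cat <- function(x) sum(x <= 3)
  hits_dist <- apply(combos, 2, in_cat)
  for (h in 0:3) {
    expected <- mean(hits_dist >= h)
    expect_equal(fisher_enrichment(h, 4, 3, 10)$p, expected,
                 tolerance = 1e-12)
  }
  # monotone non-increasing in hits
  ps <- vapply(0:3, function(h) fisher_enrichment(h, 4, 3, 10)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_equal(fisher_enrichment(0, 50, 5, 1000)$p, 1)
  expect_error(fisher_enrichment(5, 4, 3, 10), "Inconsistent")
})
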