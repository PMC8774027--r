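# Shared fixtures, all generated in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small, fast cohort used by most module tests.
small_cfg <- function(seed = 1, n_genes = 400, n_markers_per_type = 8, ...) {
  sim_config(n_genes = n_genes, n_markers_per_type = n_markers_per_type,
             seed = seed, ...)
}

small_sim <- function(seed = 1, ...) {
  cfg <- small_cfg(seed, ...)
  simulate_bulk(cfg, simulate_reference(cfg))
}

# Criterion-style single-study mixture scenario with known proportions.
mixture_cfg <- function(seed = 7, noise_sd = 0.1, n = 25) {
  sim_config(n_studies = 1, n_control = n, n_case = n, n_genes = 1000,
             dirichlet_alpha_control = rep(1, 6),
             dirichlet_alpha_case = rep(1, 6),
             study_sd = 0, noise_sd = noise_sd, n_true_degs = 0,
             gender_gene_count = 0, seed = seed)
}

# Naive O(N * n_set) enrichment-score oracle: walk the whole ranked list.
# Magnitude ties keep the earliest excursion (tolerance guards float noise).
es_oracle <- function(in_set, scores) {
  N <- length(scores)
  m <- sum(in_set)
  nr <- sum(abs(scores[in_set]))
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- run + if (in_set[i]) {
      if (nr == 0) 1 / m else abs(scores[i]) / nr
    } else {
      -1 / (N - m)
    }
    if (abs(run) > abs(best) * (1 + 1e-9)) best <- run
  }
  best
}

# Exact betweenness by all-pairs path counting (BFS distances + shortest
# path count DP), independent of igraph's Brandes implementation.
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  bw <- numeric(n)
  dist_all <- matrix(Inf, n, n)
  sigma_all <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sigma <- numeric(n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
          if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist_all[s, ] <- dist; sigma_all[s, ] <- sigma
  }
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != v && t != v && is.finite(dist_all[s, t]) &&
            dist_all[s, v] + dist_all[v, t] == dist_all[s, t]) {
          bw[v] <- bw[v] +
            sigma_all[s, v] * sigma_all[v, t] / sigma_all[s, t]
        }
      }
    }
  }
  bw
}

# Tiny synthetic single-cell matrix: cells x genes with 3 clusters and
# cluster-specific genes.
toy_cells <- function(seed = 5, cells_per = 10, n_genes = 30) {
  withr::with_seed(seed, {
    clusters <- rep(c("c1", "c2", "c3"), each = cells_per)
    m <- matrix(stats::rexp(3 * cells_per * n_genes, rate = 1),
                nrow = 3 * cells_per)
    colnames(m) <- sprintf("t%02d", seq_len(n_genes))
    rownames(m) <- sprintf("cell%02d", seq_len(nrow(m)))
    # plant exclusive genes per cluster
    for (i in 1:3) {
      g <- i  # gene index t01..t03 exclusive to cluster i
      m[, g] <- 0
      m[clusters == paste0("c", i), g] <- 5
    }
    list(m = m, clusters = clusters)
  })
}
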