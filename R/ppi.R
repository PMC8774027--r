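#' Merge protein-protein interaction edge lists into a simple graph
#'
#' Symbols are uppercased; edges with endpoints outside the optional
#' allow-list are dropped; self-loops are removed; duplicate undirected
#' pairs are collapsed with their source tags unioned; finally, nodes with
#' degree 1 are removed in a single pass (neighbors whose degree drops to 1
#' as a consequence are kept — the pruning is not iterated).
#'
#' @param edge_lists Named list of data frames, each with the two interactor
#'   columns first; the list names are the source tags. A single data frame
#'   is also accepted (source taken from a `source` column or "src1").
#' @param allow_list Optional character vector of valid (e.g. human) symbols.
#' @return An [igraph::graph] with edge attribute `sources` and the class
#'   attribute `cyto_ppi`.
#' @export
merge_networks <- function(edge_lists, allow_list = NULL) {
  if (is.data.frame(edge_lists)) {
    src <- if ("source" %in% names(edge_lists)) edge_lists$source else "src1"
    edge_lists <- split(edge_lists[, 1:2], src)
  }
  if (is.null(names(edge_lists)) || any(!nzchar(names(edge_lists)))) {
    names(edge_lists) <- paste0("src", seq_along(edge_lists))
  }
  edges <- purrr::imap_dfr(edge_lists, function(d, src) {
    tibble::tibble(a = toupper(as.character(d[[1]])),
                   b = toupper(as.character(d[[2]])), source = src)
  })
  if (!is.null(allow_list)) {
    ok <- toupper(allow_list)
    edges <- dplyr::filter(edges, .data$a %in% ok & .data$b %in% ok)
  }
  edges <- dplyr::filter(edges, .data$a != .data$b)
  edges <- dplyr::mutate(edges, lo = pmin(.data$a, .data$b),
                         hi = pmax(.data$a, .data$b))
  collapsed <- edges |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(sources = paste(sort(unique(.data$source)),
                                     collapse = ";"), .groups = "drop")
  if (!nrow(collapsed)) rlang::abort("Merged graph is empty.")
  g <- igraph::graph_from_data_frame(collapsed, directed = FALSE)
  singletons <- igraph::V(g)[igraph::degree(g) <= 1]
  g <- igraph::delete_vertices(g, singletons)
  if (igraph::vcount(g) == 0) rlang::abort("Merged graph is empty after degree-1 pruning.")
  g$cyto_ppi <- TRUE
  g
}

#' Seed neighborhood subgraph
#'
#' Node set = (seeds present in the graph) plus all their direct
#' interactors; edge set = every graph edge with both endpoints inside that
#' node set (the induced subgraph).
#'
#' @param g An igraph graph.
#' @param seeds Character vector of node names.
#' @return Induced igraph subgraph.
#' @export
ppi_neighborhood <- function(g, seeds) {
  present <- intersect(toupper(seeds), igraph::V(g)$name)
  if (!length(present)) rlang::abort("No seed is present in the graph.")
  nb <- unique(unlist(igraph::adjacent_vertices(g, present)))
  nodes <- union(present, igraph::V(g)$name[nb])
  igraph::induced_subgraph(g, nodes)
}

#' Degree and betweenness centrality table
#'
#' Exact unnormalized betweenness (Brandes' algorithm on the unweighted
#' undirected graph, equal-split credit across equal-length shortest paths,
#' computed per connected component) plus degree for every node.
#'
#' @param g An igraph graph.
#' @return Tibble: `node`, `degree`, `betweenness`.
#' @export
ppi_centrality <- function(g) {
  tibble::tibble(node = igraph::V(g)$name,
                 degree = unname(igraph::degree(g)),
                 betweenness = unname(igraph::betweenness(
                   g, directed = FALSE, normalized = FALSE, weights = NA)))
}

#' Nominate central and top-central nodes
#'
#' A node is central when both its degree and its betweenness reach the
#' nearest-rank `pct`-th percentile of the respective metric; ties at the
#' threshold value are included. Top-central nodes are the central nodes not
#' encoded by the seed DEGs themselves.
#'
#' @param tab Centrality table from [ppi_centrality()].
#' @param deg_encoded Character vector of DEG-encoded node names.
#' @param pct Percentile in (0, 100).
#' @return `tab` with logical `is_deg_encoded`, `is_central`,
#'   `is_top_central` columns; thresholds in attributes `threshold_degree`
#'   and `threshold_betweenness`.
#' @export
central_nodes <- function(tab, deg_encoded = character(), pct = 95) {
  if (!nrow(tab)) rlang::abort("Centrality table is empty.")
  if (pct <= 0 || pct >= 100) rlang::abort("`pct` must be in (0, 100).")
  thr_d <- nearest_rank_percentile(tab$degree, pct)
  thr_b <- nearest_rank_percentile(tab$betweenness, pct)
  out <- dplyr::mutate(tab,
    is_deg_encoded = toupper(.data$node) %in% toupper(deg_encoded),
    is_central = .data$degree >= thr_d & .data$betweenness >= thr_b,
    is_top_central = .data$is_central & !.data$is_deg_encoded)
  attr(out, "threshold_degree") <- thr_d
  attr(out, "threshold_betweenness") <- thr_b
  out
}

#' One-sided Fisher enrichment of a category in a drawn set
#'
#' Hypergeometric upper tail: probability of at least `hits_in_set`
#' category members when `set_size` items are drawn from a universe of
#' `universe` items containing `category_size` category members. The odds
#' ratio is the conditional maximum-likelihood estimate from the 2x2 table.
#'
#' @param hits_in_set,set_size,category_size,universe Counts.
#' @return Tibble: `odds_ratio`, `p`.
#' @export
fisher_enrichment <- function(hits_in_set, set_size, category_size, universe) {
  if (hits_in_set > min(set_size, category_size) || category_size > universe ||
      set_size > universe || any(c(hits_in_set, set_size, category_size,
                                   universe) < 0)) {
    rlang::abort("Inconsistent contingency counts.")
  }
  p <- stats::phyper(hits_in_set - 1, category_size, universe - category_size,
                     set_size, lower.tail = FALSE)
  tab <- matrix(c(hits_in_set,
                  category_size - hits_in_set,
                  set_size - hits_in_set,
                  universe - category_size - set_size + hits_in_set), 2, 2)
  or <- unname(stats::fisher.test(tab, alternative = "greater")$estimate)
  tibble::tibble(odds_ratio = or, p = p)
}
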