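#' Configuration for the multi-study bulk-mixture simulator
#'
#' Bundles every knob of the synthetic cohort: study layout, cell-type
#' composition under each condition, batch/noise scales, planted
#' condition-responsive genes, marker structure, and sex effects. Defaults
#' emulate a nine-study case/control brain cohort (70 control / 88 case
#' samples split as in typical substantia nigra microarray collections) with
#' six cell types whose proportions shift with disease: neurons decrease,
#' oligodendrocytes and endothelial cells increase.
#'
#' @param n_studies Number of studies.
#' @param n_control,n_case Per-study group sizes (recycled if scalar).
#' @param n_genes Number of simulated genes.
#' @param n_celltypes Number of cell types.
#' @param celltypes Cell-type names; defaults to ast/end/mic/neu/odc/opc when
#'   `n_celltypes` is 6, else `ct1..ctK`.
#' @param dirichlet_alpha_control,dirichlet_alpha_case Dirichlet concentration
#'   parameters for per-sample proportions in each group. The defaults put
#'   neurons at mean 0.40 in controls and 0.28 in cases (a standardized mean
#'   difference near -1), oligodendrocytes at 0.27 vs 0.35, endothelial cells
#'   at 0.07 vs 0.10.
#' @param severity_shape_control,severity_shape_case Beta shape pairs for the
#'   latent per-sample degeneration severity. Each sample's Dirichlet
#'   concentration is interpolated between the control and case alphas along
#'   its severity, so all disease-driven cell-type shifts co-vary on one
#'   axis (neuronal loss dragging the other fractions with it) rather than
#'   moving independently; the scaling keeps each group's mean concentration
#'   exactly at its stated alpha vector. Degenerate shapes `c(0, 0)` disable
#'   the severity axis and recover independent per-group draws.
#' @param study_sd SD (log2 units) of per-study, per-gene batch offsets.
#' @param noise_sd SD (log2 units) of per-measurement Gaussian noise.
#' @param n_true_degs Number of genes given a genuine condition effect.
#' @param deg_effect Magnitude (log2 fold change) of the planted effect;
#'   signs are randomized per gene.
#' @param n_markers_per_type Marker genes per cell type.
#' @param marker_lfc Minimum log2 separation of a marker's own-type signature
#'   over its maximum in any other type.
#' @param cross_type_sd SD (log2 units) of non-marker cross-cell-type
#'   expression variation. This is what makes composition shifts a
#'   genome-wide confounder rather than a marker-only one: at the default
#'   (1 log2 unit, i.e. typical two-fold differences between cell types),
#'   composition change alone pushes a few percent of non-marker genes past
#'   a 1.2-fold-change call, while the confounding still lies along the
#'   neuron/oligodendrocyte axis that the aware model corrects.
#' @param gender_gene_count Number of Y-chromosome-proxy genes.
#' @param gender_effect Log2 shift of Y-proxy genes in males.
#' @param p_male Probability a sample is male.
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 7)
#' @export
sim_config <- function(n_studies = 9,
                       n_control = c(9, 7, 6, 15, 9, 5, 8, 5, 6),
                       n_case = c(16, 9, 6, 11, 8, 6, 15, 8, 9),
                       n_genes = 2000,
                       n_celltypes = 6,
                       celltypes = NULL,
                       dirichlet_alpha_control = c(2, 1, 1, 6, 4, 1),
                       dirichlet_alpha_case = c(2, 1.5, 1, 4.2, 5.2, 1.1),
                       severity_shape_control = c(1.5, 8),
                       severity_shape_case = c(4, 3),
                       study_sd = 0.3,
                       noise_sd = 0.5,
                       n_true_degs = 30,
                       deg_effect = 1,
                       n_markers_per_type = 20,
                       marker_lfc = 2,
                       cross_type_sd = 1,
                       gender_gene_count = 10,
                       gender_effect = 2,
                       p_male = 0.6,
                       seed = 1L) {
  if (length(n_control) == 1L) n_control <- rep(n_control, n_studies)
  if (length(n_case) == 1L) n_case <- rep(n_case, n_studies)
  if (length(n_control) != n_studies || length(n_case) != n_studies) {
    rlang::abort("`n_control`/`n_case` must have length 1 or `n_studies`.")
  }
  if (is.null(celltypes)) {
    celltypes <- if (n_celltypes == 6) c("ast", "end", "mic", "neu", "odc", "opc")
                 else paste0("ct", seq_len(n_celltypes))
  }
  if (length(dirichlet_alpha_control) == 1L)
    dirichlet_alpha_control <- rep(dirichlet_alpha_control, n_celltypes)
  if (length(dirichlet_alpha_case) == 1L)
    dirichlet_alpha_case <- rep(dirichlet_alpha_case, n_celltypes)
  cfg <- list(
    n_studies = as.integer(n_studies), n_control = as.integer(n_control),
    n_case = as.integer(n_case), n_genes = as.integer(n_genes),
    n_celltypes = as.integer(n_celltypes), celltypes = celltypes,
    dirichlet_alpha_control = stats::setNames(dirichlet_alpha_control, celltypes),
    dirichlet_alpha_case = stats::setNames(dirichlet_alpha_case, celltypes),
    severity_shape_control = severity_shape_control,
    severity_shape_case = severity_shape_case,
    study_sd = study_sd, noise_sd = noise_sd,
    n_true_degs = as.integer(n_true_degs), deg_effect = deg_effect,
    n_markers_per_type = as.integer(n_markers_per_type), marker_lfc = marker_lfc,
    cross_type_sd = cross_type_sd,
    gender_gene_count = as.integer(gender_gene_count),
    gender_effect = gender_effect, p_male = p_male, seed = as.integer(seed)
  )
  counts <- c(cfg$n_studies, cfg$n_control, cfg$n_case, cfg$n_genes,
              cfg$n_celltypes, cfg$n_markers_per_type)
  if (any(counts < 1L)) rlang::abort("All counts must be >= 1.")
  if (cfg$n_true_degs < 0L || cfg$gender_gene_count < 0L) {
    rlang::abort("`n_true_degs` and `gender_gene_count` must be >= 0.")
  }
  if (study_sd < 0 || noise_sd < 0 || cross_type_sd < 0) {
    rlang::abort("Standard deviations must be >= 0.")
  }
  if (any(dirichlet_alpha_control <= 0) || any(dirichlet_alpha_case <= 0)) {
    rlang::abort("Dirichlet alphas must be > 0.")
  }
  if (length(cfg$dirichlet_alpha_control) != n_celltypes ||
      length(cfg$dirichlet_alpha_case) != n_celltypes) {
    rlang::abort("Dirichlet alpha vectors must match `n_celltypes`.")
  }
  if (cfg$n_markers_per_type * cfg$n_celltypes > cfg$n_genes) {
    rlang::abort("n_markers_per_type * n_celltypes exceeds n_genes.")
  }
  structure(cfg, class = "sim_config")
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Mix cell-type signatures into log2 bulk profiles
#'
#' The noiseless core of the generative model: mixing happens on the linear
#' scale, log2 is applied afterwards. Degenerate one-hot proportion rows
#' therefore return exactly the log2 of the corresponding reference row.
#'
#' @param proportions Samples x cell types matrix, rows on the simplex.
#' @param reference Cell types x genes linear-scale matrix.
#' @return Genes x samples log2 matrix.
#' @export
mix_bulk <- function(proportions, reference) {
  proportions <- as.matrix(proportions)
  if (ncol(proportions) != nrow(reference)) {
    rlang::abort("Cell-type dimensions of `proportions` and `reference` disagree.")
  }
  out <- t(log2(proportions %*% reference))
  colnames(out) <- rownames(proportions)
  out
}

#' Simulate a cell-type reference signature matrix with markers
#'
#' Draws a linear-scale cell-type-by-gene signature matrix. Marker genes are
#' planted so that their own-type signature exceeds their maximum in every
#' other type by at least `marker_lfc` log2 units; non-marker genes vary
#' across types with SD `cross_type_sd` around a shared gene baseline.
#'
#' @param config A [sim_config()].
#' @return List with `reference` (cell types x genes, linear scale, non
#'   negative) and `marker_map` (named list: cell type -> marker gene ids).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 101L, {
    k <- config$n_celltypes
    g <- config$n_genes
    ids <- gene_ids(g)
    base <- stats::rnorm(g, mean = 6, sd = 1.2)
    ref <- 2^(matrix(rep(base, each = k), nrow = k) +
                matrix(stats::rnorm(k * g, 0, config$cross_type_sd), nrow = k))
    dimnames(ref) <- list(config$celltypes, ids)
    n_mark <- config$n_markers_per_type
    marker_genes <- sample(ids, n_mark * k)
    marker_map <- split(marker_genes, rep(config$celltypes, each = n_mark))
    marker_map <- marker_map[config$celltypes]
    for (t in config$celltypes) {
      for (gm in marker_map[[t]]) {
        others <- setdiff(config$celltypes, t)
        ref[others, gm] <- 2^(base[match(gm, ids)] +
                                stats::rnorm(k - 1, 0, 0.5))
        ref[t, gm] <- max(ref[others, gm]) *
          2^(config$marker_lfc + stats::runif(1, 0.05, 0.35))
      }
    }
    list(reference = ref, marker_map = marker_map)
  })
}

#' Simulate multi-study bulk mixtures with exported ground truth
#'
#' Per-sample cell-type proportions are Dirichlet draws (group-specific
#' concentrations), mixed with the linear-scale reference, log2-transformed,
#' and then perturbed additively on the log2 scale by per-study batch
#' offsets, planted condition effects (true DEGs, case samples only), a male
#' shift on Y-proxy genes, and Gaussian noise. Per-study random substreams
#' are derived from the global seed by fixed offsets, so adding a study
#' leaves earlier studies' data unchanged.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()] built from the same
#'   config (dimensions are checked).
#' @return List of class `cyto_sim`: `expr` (genes x samples log2 matrix),
#'   `meta` (tibble: sample_id, study_id, status, gender, age, braak), and
#'   `truth` with `true_proportions` (tibble), `true_degs` (tibble gene_id,
#'   effect), `marker_map`, `gender_labels`, `gender_gene_ids`, and
#'   `study_offsets` (study x gene matrix) — enough to reconstruct the bulk
#'   matrix exactly when `noise_sd = 0`.
#' @export
simulate_bulk <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  ref <- reference$reference
  if (!is.matrix(ref) || ncol(ref) != config$n_genes ||
      nrow(ref) != config$n_celltypes) {
    rlang::abort("`reference` dimensions do not match `config`.")
  }
  ids <- colnames(ref)
  k <- config$n_celltypes

  marker_genes <- unlist(reference$marker_map, use.names = FALSE)
  glob <- withr::with_seed(config$seed + 211L, {
    eligible <- setdiff(ids, marker_genes)
    deg_ids <- sample(eligible, config$n_true_degs)
    deg_sign <- sample(c(-1, 1), config$n_true_degs, replace = TRUE)
    gender_ids <- sample(setdiff(eligible, deg_ids), config$gender_gene_count)
    list(deg_ids = deg_ids, deg_sign = deg_sign, gender_ids = gender_ids)
  })
  deg_idx <- match(glob$deg_ids, ids)
  gender_idx <- match(glob$gender_ids, ids)

  expr_cols <- list(); meta_rows <- list(); prop_rows <- list()
  sev_rows <- list()
  offsets <- matrix(0, config$n_studies, config$n_genes,
                    dimnames = list(paste0("study", seq_len(config$n_studies)), ids))
  for (s in seq_len(config$n_studies)) {
    n_c <- config$n_control[s]; n_k <- config$n_case[s]; n <- n_c + n_k
    study <- paste0("study", s)
    res <- withr::with_seed(config$seed + 1000L * s, {
      off <- stats::rnorm(config$n_genes, 0, config$study_sd)
      status <- rep(c("control", "case"), c(n_c, n_k))
      shp_c <- config$severity_shape_control
      shp_k <- config$severity_shape_case
      d_alpha <- config$dirichlet_alpha_case - config$dirichlet_alpha_control
      if (all(shp_c > 0) && all(shp_k > 0) && any(d_alpha != 0)) {
        # latent degeneration severity: one axis drives every cell-type
        # shift jointly; centred scaling keeps each group's mean alpha at
        # its stated vector
        sev <- c(stats::rbeta(n_c, shp_c[1], shp_c[2]),
                 stats::rbeta(n_k, shp_k[1], shp_k[2]))
        m_c <- shp_c[1] / sum(shp_c); m_k <- shp_k[1] / sum(shp_k)
        frac <- (sev - m_c) / (m_k - m_c)
        alpha <- outer(frac, d_alpha) +
          rep(config$dirichlet_alpha_control, each = n)
        alpha <- pmax(alpha, 0.15)
        props <- t(vapply(seq_len(n), function(i) rdirichlet(1, alpha[i, ])[1, ],
                          numeric(config$n_celltypes)))
      } else {
        sev <- rep(NA_real_, n)
        props <- rbind(rdirichlet(n_c, config$dirichlet_alpha_control),
                       rdirichlet(n_k, config$dirichlet_alpha_case))
      }
      gender <- ifelse(stats::runif(n) < config$p_male, "M", "F")
      age <- round(stats::rnorm(n, 75, 8))
      braak <- ifelse(status == "case", sample(3:6, n, replace = TRUE),
                      sample(0:2, n, replace = TRUE))
      m <- t(log2(props %*% ref))  # genes x samples
      m <- m + off
      eff <- glob$deg_sign * config$deg_effect
      m[deg_idx, status == "case"] <- m[deg_idx, status == "case"] + eff
      m[gender_idx, gender == "M"] <- m[gender_idx, gender == "M"] +
        config$gender_effect
      m <- m + matrix(stats::rnorm(length(m), 0, config$noise_sd), nrow = nrow(m))
      list(off = off, props = props, status = status, gender = gender,
           age = age, braak = braak, m = m, sev = sev)
    })
    sample_id <- sprintf("s%d_%02d", s, seq_len(n))
    colnames(res$m) <- sample_id
    rownames(res$m) <- ids
    offsets[s, ] <- res$off
    expr_cols[[s]] <- res$m
    meta_rows[[s]] <- tibble::tibble(
      sample_id = sample_id, study_id = study, status = res$status,
      gender = res$gender, age = res$age, braak = res$braak)
    colnames(res$props) <- config$celltypes
    prop_rows[[s]] <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                                       tibble::as_tibble(res$props))
    sev_rows[[s]] <- res$sev
  }
  meta <- dplyr::bind_rows(meta_rows)
  truth <- list(
    true_proportions = dplyr::bind_rows(prop_rows),
    true_degs = tibble::tibble(gene_id = glob$deg_ids,
                               effect = glob$deg_sign * config$deg_effect),
    marker_map = reference$marker_map,
    gender_labels = meta[, c("sample_id", "gender")],
    gender_gene_ids = glob$gender_ids,
    study_offsets = offsets,
    severity = stats::setNames(unlist(sev_rows), meta$sample_id)
  )
  structure(list(expr = do.call(cbind, expr_cols), meta = meta, truth = truth),
            class = "cyto_sim")
}

#' Simulate a protein-protein interaction edge list with planted hubs
#'
#' Erdos-Renyi background at the requested edge density plus `n_hubs`
#' planted hub nodes each attached to at least 30% of all nodes. The result
#' is a simple undirected graph: no self-loops, no duplicate pairs.
#'
#' @param n_nodes,n_hubs Node and hub counts (`n_hubs < n_nodes`).
#' @param edge_density Background edge probability, in (0, 1).
#' @param seed Integer seed.
#' @return Tibble with columns `a`, `b`, `source`; planted hub names in
#'   `attr(, "hubs")`.
#' @export
simulate_ppi <- function(n_nodes, n_hubs, edge_density, seed = 1L) {
  if (n_hubs >= n_nodes) rlang::abort("`n_hubs` must be < `n_nodes`.")
  if (edge_density <= 0 || edge_density >= 1) {
    rlang::abort("`edge_density` must lie strictly between 0 and 1.")
  }
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  hubs <- nodes[seq_len(n_hubs)]
  withr::with_seed(as.integer(seed) + 977L, {
    pairs <- utils::combn(n_nodes, 2)
    keep <- stats::runif(ncol(pairs)) < edge_density
    a <- pairs[1, keep]; b <- pairs[2, keep]
    for (h in seq_len(n_hubs)) {
      deg_target <- ceiling(0.35 * n_nodes)
      targets <- sample(setdiff(seq_len(n_nodes), h), deg_target)
      a <- c(a, pmin(h, targets)); b <- c(b, pmax(h, targets))
    }
    key <- paste(a, b)
    dup <- duplicated(key)
    edges <- tibble::tibble(a = nodes[a[!dup]], b = nodes[b[!dup]],
                            source = "sim")
    attr(edges, "hubs") <- hubs
    edges
  })
}
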