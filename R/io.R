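#' Read / write genes-by-samples expression TSV
#'
#' The first column holds gene ids; remaining columns are samples. Empty
#' cells become `NA` (genes a platform does not probe).
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param mat Genes x samples matrix.
#' @export
write_expression <- function(mat, path) {
  d <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(mat)),
                        tibble::as_tibble(mat))
  readr::write_tsv(d, path)
}

#' Read / write sample metadata TSV
#'
#' Expected columns: `sample_id`, `study_id`, `status`, `gender`, optional
#' `age`, `braak`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "study_id", "status")
  if (!all(need %in% names(d))) {
    rlang::abort(sprintf("Metadata must contain: %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(d$sample_id)) rlang::abort("Duplicate sample_id in metadata.")
  d
}

#' @rdname read_metadata
#' @param meta Metadata tibble.
#' @export
write_metadata <- function(meta, path) readr::write_tsv(meta, path)

#' Read / write a marker panel (JSON: cell type -> ordered gene list)
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_marker_panel <- function(path) {
  panel <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(panel, as.character)
}

#' @rdname read_marker_panel
#' @param panel Named list of character vectors.
#' @export
write_marker_panel <- function(panel, path) {
  jsonlite::write_json(panel, path, pretty = TRUE)
}

#' Read a probe-to-gene map TSV (`probe_id`, `gene_id`)
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_probe_map <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(d))) {
    rlang::abort("Probe map needs `probe_id` and `gene_id` columns.")
  }
  d
}

#' Read a source-tagged PPI edge-list TSV
#'
#' First two columns are interactor symbols; an optional `source` column
#' tags the database of origin.
#'
#' @param path File path.
#' @param source Fallback source tag when the file has no `source` column.
#' @return Tibble `a`, `b`, `source`.
#' @export
read_edge_list <- function(path, source = "unknown") {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(d) < 2) rlang::abort("Edge list needs at least two columns.")
  tibble::tibble(a = as.character(d[[1]]), b = as.character(d[[2]]),
                 source = if ("source" %in% names(d)) d$source else source)
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path))
  unique(x[nzchar(x)])
}

#' Export a simulated cohort to plain-text files
#'
#' Writes the expression TSV, metadata TSV, marker-panel JSON and a
#' ground-truth JSON (true proportions, planted DEGs, Y-proxy gene ids,
#' gender labels) into `dir`.
#'
#' @param sim A `cyto_sim` object from [simulate_bulk()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cyto_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             markers = file.path(dir, "marker_panel.json"),
             truth = file.path(dir, "ground_truth.json"))
  write_expression(sim$expr, paths["expression"])
  write_metadata(sim$meta, paths["metadata"])
  write_marker_panel(sim$truth$marker_map, paths["markers"])
  jsonlite::write_json(
    list(true_proportions = sim$truth$true_proportions,
         true_degs = sim$truth$true_degs,
         gender_gene_ids = sim$truth$gender_gene_ids,
         gender_labels = sim$truth$gender_labels),
    paths["truth"], pretty = TRUE, digits = NA)
  invisible(paths)
}
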