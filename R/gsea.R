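#' Rank genes for preranked GSEA
#'
#' Score = `-log10(p_adj) * sign(beta_status)`, with adjusted p-values
#' floored at 1e-300 before the logarithm. The list is sorted in descending
#' score order with ties broken by gene id so runs are deterministic.
#'
#' @param tab DE table with `gene_id`, `p_adj`, `beta_status`.
#' @return Tibble `item`, `score`, descending.
#' @export
rank_genes <- function(tab) {
  bad <- is.na(tab$p_adj) | is.na(tab$beta_status)
  if (any(bad)) {
    rlang::abort(sprintf("Missing p_adj/beta_status for: %s",
                         paste(tab$gene_id[bad], collapse = ", ")))
  }
  score <- -log10(pmax(tab$p_adj, 1e-300)) * sign(tab$beta_status)
  tibble::tibble(item = tab$gene_id, score = score) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$item)
}

#' Read a GMT gene-set file
#'
#' Standard dialect: tab-separated lines, field 1 the set name, field 2 a
#' description, fields 3+ the genes. Duplicate genes within a set are
#' deduplicated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), descriptions = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    rlang::abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                         paste(short, collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[`, character(1), 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, unname(desc[nm]), sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
}

# Signed extremum of the weighted running sum for hit positions `pos`
# (ascending ranks) on a list of length N with |score| vector abs_s.
es_stat <- function(pos, abs_s, N) {
  pos <- sort(pos)
  m <- length(pos)
  w <- abs_s[pos]
  nr <- sum(w)
  if (nr == 0) w[] <- 1 / m else w <- w / nr
  d <- 1 / (N - m)
  H <- cumsum(w)
  after <- H - (pos - seq_len(m)) * d
  before <- c(0, H[-m]) - (pos - seq_len(m)) * d  # just before each hit
  # interleave in list-position order so |.|-ties resolve to the earliest
  # extremum, exactly as a full walk over the ranked list would; magnitude
  # ties (the +/- excursions are often rational multiples of the same step)
  # are compared with a relative tolerance so float noise cannot flip signs
  cand <- as.vector(rbind(before, after))
  top <- max(abs(cand))
  cand[which(abs(cand) >= top * (1 - 1e-9))[1]]
}

#' Preranked gene-set enrichment with a gene-label permutation null
#'
#' Enrichment score per set = the signed maximum deviation of the weighted
#' running sum over the ranked list (hit increments proportional to
#' `|score|`, weight exponent 1; miss decrements `1/(N - set size)`). The
#' null distribution re-draws random same-size gene-label sets; the
#' one-tailed p compares against null scores of the same sign,
#' `p = (1 + #{|null| >= |ES|, same sign}) / (1 + #{same sign})`, and
#' `NES = ES / mean(|null ES of matching sign|)`. Benjamini-Hochberg
#' correction is applied across the tested sets.
#'
#' @param ranks Tibble `item`, `score` (see [rank_genes()]) or a named
#'   numeric vector. Re-sorted descending with id tie-break.
#' @param sets Named list of character vectors; restricted to items present
#'   in `ranks` before the size filter.
#' @param n_perm Number of permutation sets per gene set.
#' @param min_size,max_size Post-restriction set-size filter.
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param exhaustive If `TRUE` and `choose(N, m)` <= `exhaustive_limit`,
#'   enumerate every same-size label set instead of sampling (exact null).
#' @param exhaustive_limit Cap on enumeration size.
#' @return Tibble of class `cyto_gsea`: `set_id`, `es`, `nes`, `p`, `p_adj`,
#'   `set_size_used`.
#' @export
gsea_preranked <- function(ranks, sets, n_perm = 100000, min_size = 15,
                           max_size = 500, seed = 1L, exhaustive = FALSE,
                           exhaustive_limit = 2e5) {
  if (is.numeric(ranks) && !is.null(names(ranks))) {
    ranks <- tibble::tibble(item = names(ranks), score = unname(ranks))
  }
  if (!all(is.finite(ranks$score))) rlang::abort("Scores must be finite.")
  ranks <- dplyr::arrange(ranks, dplyr::desc(.data$score), .data$item)
  N <- nrow(ranks)
  abs_s <- abs(ranks$score)
  idx <- stats::setNames(seq_len(N), ranks$item)
  restricted <- lapply(sets, function(s) unname(idx[unique(s)[unique(s) %in% names(idx)]]))
  sizes <- lengths(restricted)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) {
    rlang::warn("No gene set passes the size filter.")
    return(structure(tibble::tibble(set_id = character(), es = numeric(),
                                    nes = numeric(), p = numeric(),
                                    p_adj = numeric(),
                                    set_size_used = integer()),
                     class = c("cyto_gsea", class(tibble::tibble()))))
  }
  restricted <- restricted[keep]
  out <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(names(restricted), function(nm) {
      pos <- restricted[[nm]]
      m <- length(pos)
      es <- es_stat(pos, abs_s, N)
      null_es <- if (exhaustive && choose(N, m) <= exhaustive_limit) {
        apply(utils::combn(N, m), 2, es_stat, abs_s = abs_s, N = N)
      } else {
        vapply(seq_len(n_perm),
               function(i) es_stat(sample.int(N, m), abs_s, N), numeric(1))
      }
      same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      # null magnitudes equal to |ES| count as at least as extreme; compare
      # with a relative tolerance since equal excursions can be reached by
      # different float paths
      p <- (1 + sum(abs(same) >= abs(es) * (1 - 1e-9))) / (1 + length(same))
      nes <- if (es == 0 || !length(same)) 0 else es / mean(abs(same))
      tibble::tibble(set_id = nm, es = es, nes = nes, p = p,
                     set_size_used = m)
    })
  })
  out$p_adj <- bh_adjust(out$p)
  out <- dplyr::relocate(out, "p_adj", .after = "p")
  class(out) <- c("cyto_gsea", class(out))
  out
}
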