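#' Central window of a coding region
#'
#' Insertions near the extreme ends of a coding region often leave a
#' functional protein, so library curation keeps only insertions in the
#' central fraction (default 90%) of each gene. The window trims
#' `ceil(L * (1 - fraction) / 2)` positions from each end of a gene of
#' length `L = end - start + 1`, so at most `fraction * L` positions
#' qualify; both bounds are inclusive.
#'
#' @param genes Tibble of gene models (columns `start`, `end`).
#' @param fraction Central fraction to keep, in (0, 1]; default 0.9.
#' @return `genes` with added columns `window_low`, `window_high`.
#' @export
#' @examples
#' central_window(tibble::tibble(gene_id = "g", start = 1, end = 100))
central_window <- function(genes, fraction = 0.9) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("fraction must be a single number in (0, 1]")
  }
  len <- genes$end - genes$start + 1
  trim <- ceiling(len * (1 - fraction) / 2)
  mutate(genes, window_low = .data$start + trim, window_high = .data$end - trim)
}

#' Assign insertion sites to genes under the central-window rule
#'
#' Each site is assigned to every gene whose central window contains its
#' position (overlapping genes each receive the site; fitness is computed
#' per gene independently). Strand is ignored: a transposon insertion
#' disrupts a coding region on either strand. Sites outside all windows
#' (including sites on unannotated replicons) stay unassigned but remain
#' part of the pool totals reported in the library.
#'
#' @param sites Site-by-sample tibble (columns `replicon_id`, `position`,
#'   plus count columns) as from [combine_wigs()].
#' @param genes Gene-model tibble as from [read_annotation()].
#' @param fraction Central fraction, passed to [central_window()].
#' @return An object of class `curated_library`: a list with
#'   `assignments` (tibble `gene_id`, `replicon_id`, `position`,
#'   `multi_gene` flag), `n_unique_mutants`, `n_curated_mutants`
#'   (distinct curated sites), `mean_mutants_per_gene`
#'   (curated sites / genes in the annotation), `n_genes`, and `fraction`.
#' @export
assign_sites <- function(sites, genes, fraction = 0.9) {
  if (nrow(genes) == 0) abort("empty gene set")
  win <- central_window(genes, fraction)
  ok <- win$window_low <= win$window_high
  win_gr <- GenomicRanges::GRanges(
    seqnames = win$replicon_id[ok],
    ranges = IRanges::IRanges(start = win$window_low[ok],
                              end = win$window_high[ok])
  )
  site_gr <- GenomicRanges::GRanges(
    seqnames = sites$replicon_id,
    ranges = IRanges::IRanges(start = sites$position, width = 1)
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(site_gr, win_gr, ignore.strand = TRUE)
  )
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  assignments <- tibble(
    gene_id = win$gene_id[ok][gi],
    replicon_id = sites$replicon_id[si],
    position = sites$position[si]
  )
  multi <- duplicated(si) | duplicated(si, fromLast = TRUE)
  assignments$multi_gene <- multi
  n_curated <- length(unique(si))
  structure(
    list(
      assignments = assignments,
      n_unique_mutants = nrow(sites),
      n_curated_mutants = n_curated,
      mean_mutants_per_gene = n_curated / nrow(genes),
      n_genes = nrow(genes),
      fraction = fraction
    ),
    class = "curated_library"
  )
}

#' @export
print.curated_library <- function(x, ...) {
  cat(sprintf(
    "curated_library: %d unique mutants, %d curated (central %.0f%%), %d genes, %.1f mutants/gene\n",
    x$n_unique_mutants, x$n_curated_mutants, 100 * x$fraction,
    x$n_genes, x$mean_mutants_per_gene
  ))
  invisible(x)
}

#' Summarise a curated mutant library
#'
#' @param lib A `curated_library` from [assign_sites()].
#' @param genes The gene-model tibble the library was built from.
#' @return One-row tibble: total genes, genes hit by at least one curated
#'   site, fraction hit, unique and curated mutant counts, mean curated
#'   mutants per annotated gene, and insertion density (curated sites per
#'   kb of annotated gene span).
#' @export
library_summary <- function(lib, genes) {
  hit <- unique(lib$assignments$gene_id)
  gene_bp <- sum(genes$end - genes$start + 1)
  tibble(
    genes_total = nrow(genes),
    genes_hit = length(hit),
    fraction_hit = if (nrow(genes) > 0) length(hit) / nrow(genes) else NA_real_,
    n_unique_mutants = lib$n_unique_mutants,
    n_curated_mutants = lib$n_curated_mutants,
    mean_mutants_per_gene = lib$mean_mutants_per_gene,
    insertions_per_kb = if (gene_bp > 0) 1000 * lib$n_curated_mutants / gene_bp
                        else NA_real_
  )
}
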