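#' Grand-mean normalization of a count matrix
#'
#' Scales every sample to the grand mean of per-sample totals: sample `s`
#' is multiplied by `mean(totals) / total_s`, so after normalization every
#' sample total equals the grand mean. Normalized counts are left
#' fractional; frequencies are ratios, so re-rounding would only add error.
#'
#' @param counts Tibble with one or more numeric sample columns (plus any
#'   key columns such as `replicon_id`/`position` or `gene_id`).
#' @param samples Character vector naming the sample columns; defaults to
#'   every numeric column except `position`, `start`, `end`.
#' @return List with `counts` (normalized tibble, same shape) and
#'   `scale_factors` (named numeric).
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = c("a", "b"), s1 = c(40, 60), s2 = c(100, 200))
#' grand_mean_normalize(m, c("s1", "s2"))$scale_factors
grand_mean_normalize <- function(counts, samples = NULL) {
  samples <- samples %||% setdiff(
    names(counts)[vapply(counts, is.numeric, logical(1))],
    c("position", "start", "end", "replicate", "day")
  )
  if (length(samples) < 1) abort("no sample columns to normalize")
  totals <- vapply(samples, function(s) sum(counts[[s]]), numeric(1))
  if (any(totals <= 0)) {
    abort(paste0("sample(s) with zero total reads: ",
                 paste(samples[totals <= 0], collapse = ", ")))
  }
  grand <- mean(totals)
  scale <- grand / totals
  for (s in samples) counts[[s]] <- counts[[s]] * scale[[s]]
  list(counts = counts, scale_factors = setNames(scale, samples))
}

#' Sum site-level counts within genes
#'
#' Reads mapping to each unique insertion are summed within the gene the
#' site is assigned to, yielding a gene-by-sample count matrix.
#'
#' @param sites Site-by-sample tibble (normalized or raw).
#' @param lib A `curated_library` from [assign_sites()].
#' @param samples Sample columns; default all numeric except `position`.
#' @return Tibble with `gene_id` plus one column per sample.
#' @export
aggregate_by_gene <- function(sites, lib, samples = NULL) {
  samples <- samples %||% setdiff(
    names(sites)[vapply(sites, is.numeric, logical(1))], "position"
  )
  joined <- inner_join(
    lib$assignments[, c("gene_id", "replicon_id", "position")],
    sites,
    by = c("replicon_id", "position")
  )
  out <- joined %>%
    group_by(.data$gene_id) %>%
    summarise(across(all_of(samples), sum), .groups = "drop")
  arrange(out, .data$gene_id)
}

#' Remove genes with too few reads across the two timepoints
#'
#' A gene is removed when the average of its mean read count over the
#' initial samples and its mean over the final samples is below
#' `threshold` (strict inequality; the default 10 reads matches standard
#' practice for unreliable frequency estimates).
#'
#' @param gene_counts Gene-by-sample tibble from [aggregate_by_gene()].
#' @param initial_samples,final_samples Disjoint, non-empty character
#'   vectors of sample columns (inoculum aliquots and grown samples).
#' @param threshold Removal threshold (default 10).
#' @return List with `retained` (character vector of gene ids) and
#'   `removed` (tibble `gene_id`, `mean_initial`, `mean_final`,
#'   `mean_overall`).
#' @export
low_count_filter <- function(gene_counts, initial_samples, final_samples,
                             threshold = 10) {
  if (length(initial_samples) == 0 || length(final_samples) == 0) {
    abort("initial and final sample sets must be non-empty")
  }
  if (length(intersect(initial_samples, final_samples)) > 0) {
    abort("initial and final sample sets must be disjoint")
  }
  mi <- rowMeans(as.matrix(gene_counts[, initial_samples, drop = FALSE]))
  mf <- rowMeans(as.matrix(gene_counts[, final_samples, drop = FALSE]))
  overall <- (mi + mf) / 2
  drop <- overall < threshold
  list(
    retained = gene_counts$gene_id[!drop],
    removed = tibble(
      gene_id = gene_counts$gene_id[drop],
      mean_initial = mi[drop],
      mean_final = mf[drop],
      mean_overall = overall[drop]
    )
  )
}
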