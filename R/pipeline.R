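#' Run the full fitness pipeline on a site-by-sample count matrix
#'
#' Curation (central-window site assignment), grand-mean normalization,
#' gene-level aggregation, per-treatment low-count filtering, relative
#' fitness per replicate, and multispecies-vs-reference contrasts with
#' randomization tests and Benjamini-Hochberg adjustment.
#'
#' @param site_counts Site-by-sample tibble (from [combine_wigs()] or a
#'   simulated experiment's `counts`).
#' @param annotation Gene-model tibble (from [read_annotation()]).
#' @param metadata Sample metadata tibble.
#' @param expansion Tibble `treatment`, `replicate`, `d`; computed with
#'   [expansion_table()] from `cell_abundance` when omitted.
#' @param cell_abundance Cell-abundance tibble (used only when
#'   `expansion` is missing).
#' @param fraction Central window fraction (default 0.9).
#' @param threshold Low-count removal threshold (default 10).
#' @param reference Reference treatment (default `"Rp"`).
#' @param psi Pseudocount (default 0.01).
#' @param alpha Significance level (default 0.05).
#' @param n_perm Randomization-test permutations (default 10000).
#' @param seed Experiment-level seed for the sampling branch of the
#'   randomization test.
#' @param species Focal species for growth accounting (default `"Rp"`).
#' @return List with `library`, `library_summary`, `scale_factors`,
#'   `gene_counts`, `expansion`, `fitness`, `gene_fitness`, `contrasts`.
#' @export
phycofit_pipeline <- function(site_counts, annotation, metadata,
                              expansion = NULL, cell_abundance = NULL,
                              fraction = 0.9, threshold = 10,
                              reference = "Rp", psi = 0.01, alpha = 0.05,
                              n_perm = 10000, seed = NULL,
                              species = "Rp") {
  validate_annotation(annotation)
  validate_metadata(metadata)
  if (is.null(expansion)) {
    if (is.null(cell_abundance)) {
      abort("provide either expansion or cell_abundance")
    }
    expansion <- expansion_table(cell_abundance, species = species)
  }
  samples <- metadata$sample_id
  missing <- setdiff(samples, names(site_counts))
  if (length(missing) > 0) {
    abort(paste0("samples missing from count matrix: ",
                 paste(missing, collapse = ", ")))
  }
  lib <- assign_sites(site_counts, annotation, fraction)
  norm <- grand_mean_normalize(site_counts, samples)
  gene_counts <- aggregate_by_gene(norm$counts, lib, samples)
  fitness <- fitness_table(gene_counts, metadata, expansion,
                           threshold = threshold)
  contrasts <- contrast_fitness(fitness, reference = reference, psi = psi,
                                alpha = alpha, n_perm = n_perm, seed = seed)
  list(
    library = lib,
    library_summary = library_summary(lib, annotation),
    scale_factors = norm$scale_factors,
    gene_counts = gene_counts,
    expansion = expansion,
    fitness = fitness,
    gene_fitness = gene_fitness(fitness),
    contrasts = contrasts
  )
}

#' Run the pipeline directly on a simulated experiment
#'
#' Convenience wrapper: feeds a [simulate_experiment()] object through
#' [phycofit_pipeline()] with matching defaults, using growth accounting
#' on the simulated cell-abundance records.
#'
#' @param sim A `phycofit_sim`.
#' @param ... Passed to [phycofit_pipeline()].
#' @return The pipeline result list, plus `truth` carried over.
#' @export
run_sim_pipeline <- function(sim, ...) {
  counts <- sim$counts
  samples <- sim$metadata$sample_id
  totals <- rowSums(as.matrix(counts[, samples, drop = FALSE]))
  counts <- counts[totals > 0, , drop = FALSE]
  res <- phycofit_pipeline(
    counts, sim$annotation, sim$metadata,
    cell_abundance = sim$cell_abundance,
    reference = sim$config$treatments[[1]],
    psi = sim$config$psi,
    seed = sim$config$seed,
    ...
  )
  res$truth <- sim$truth
  res
}
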