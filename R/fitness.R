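#' Per-gene mutant frequencies in one sample
#'
#' @param gene_counts Gene-by-sample tibble.
#' @param sample Sample column name.
#' @return Named numeric vector of frequencies summing to 1 over genes.
#' @export
mutant_frequency <- function(gene_counts, sample) {
  x <- gene_counts[[sample]]
  total <- sum(x)
  if (!is.finite(total) || total <= 0) {
    abort(paste0("sample '", sample, "' has zero total count"))
  }
  setNames(x / total, gene_counts$gene_id)
}

#' Relative fitness of a mutant in a pooled competition
#'
#' The relative fitness of a mutant compares its exponential growth over
#' the experiment with that of the combined mutant pool:
#' \deqn{W = \frac{\ln(N_{t2} \, d / N_{t1} + 1)}
#'            {\ln((1 - N_{t2}) \, d / (1 - N_{t1}) + 1)}}
#' where `N_t1`, `N_t2` are the mutant's pool frequencies at the start and
#' end and `d` is the pool expansion factor. A neutral mutant
#' (`N_t1 == N_t2`) has `W = 1`; an extinct mutant (`N_t2 == 0`) has
#' `W = 0`; a mutant whose per-cell expansion is `d^(1/2)` approaches
#' `W = 0.5` as `d` grows.
#'
#' Undefined cases propagate as `NA` rather than being clamped: `N_t1 = 0`
#' with `N_t2 > 0` (no denominator frequency) and `N_t2 = 1` (the
#' denominator logarithm vanishes).
#'
#' @param n1,n2 Frequencies at the start and end, in `[0, 1]`.
#' @param d Pool expansion factor(s), `> 0`.
#' @return Numeric vector of fitness values (`>= 0`, or `NA`).
#' @export
#' @examples
#' relative_fitness(0.001, 0.001, 32) # neutral -> 1
#' relative_fitness(0.01, 0.02, 10)
relative_fitness <- function(n1, n2, d) {
  n <- max(length(n1), length(n2), length(d))
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n); d <- rep_len(d, n)
  if (any(d <= 0, na.rm = TRUE)) abort("expansion factor d must be > 0")
  if (any(n1 < 0 | n1 > 1 | n2 < 0 | n2 > 1, na.rm = TRUE)) {
    abort("frequencies must lie in [0, 1]")
  }
  w <- rep(NA_real_, n)
  bad <- is.na(n1) | is.na(n2) | is.na(d) |
    (n1 == 0 & n2 > 0) |  # undefined ratio
    (n1 == 0 & n2 == 0) | # mutant absent entirely
    n2 >= 1 | n1 >= 1     # denominator argument degenerates
  ok <- !bad
  if (any(ok)) {
    num <- log(n2[ok] * d[ok] / n1[ok] + 1)
    den <- log((1 - n2[ok]) * d[ok] / (1 - n1[ok]) + 1)
    w[ok] <- num / den
  }
  # exact anchors, immune to floating-point wobble
  w[ok & n2 == 0] <- 0
  neutral <- ok & n1 == n2
  w[neutral] <- 1
  w
}

#' Per-gene, per-replicate fitness table
#'
#' Runs the fitness stage of the pipeline for every non-inoculum treatment:
#' per-treatment low-count filtering against the inoculum aliquots,
#' frequency computation over the retained (curated, filtered) genes, and
#' the relative-fitness statistic per replicate. Start frequencies `N_t1`
#' are the mean over the sequenced inoculum aliquots (aliquots are not
#' paired to flasks); set `pair_inoculum = TRUE` to pair aliquot *k* with
#' replicate *k* instead.
#'
#' @param gene_counts Normalized gene-by-sample tibble
#'   (from [aggregate_by_gene()] after [grand_mean_normalize()]).
#' @param metadata Sample metadata tibble (see [read_sample_metadata()]).
#' @param expansion Tibble `treatment`, `replicate`, `d` (per-replicate
#'   expansion factors, e.g. from [expansion_table()]); a treatment-mean
#'   `d` is used when `per_replicate_d = FALSE`.
#' @param threshold Low-count removal threshold (see [low_count_filter()]).
#' @param pair_inoculum Pair inoculum aliquots to replicates instead of
#'   averaging them.
#' @param per_replicate_d Use each replicate's own `d` (default) or the
#'   treatment mean.
#' @return Tibble `gene_id`, `treatment`, `replicate`, `N_t1`, `N_t2`,
#'   `d`, `W`.
#' @export
fitness_table <- function(gene_counts, metadata, expansion, threshold = 10,
                          pair_inoculum = FALSE, per_replicate_d = TRUE) {
  validate_metadata(metadata)
  inoc <- metadata$sample_id[metadata$treatment == "inoculum"]
  if (length(inoc) == 0) abort("metadata contains no inoculum samples")
  treatments <- setdiff(unique(metadata$treatment), "inoculum")
  out <- list()
  for (tr in treatments) {
    ms <- metadata[metadata$treatment == tr & metadata$timepoint == "t2", ]
    ms <- ms[order(ms$replicate), ]
    if (nrow(ms) == 0) next
    flt <- low_count_filter(gene_counts, inoc, ms$sample_id, threshold)
    sub <- gene_counts[gene_counts$gene_id %in% flt$retained, , drop = FALSE]
    if (nrow(sub) == 0) next
    f_inoc <- vapply(inoc, function(s) mutant_frequency(sub, s),
                     numeric(nrow(sub)))
    if (nrow(sub) == 1) f_inoc <- matrix(f_inoc, nrow = 1)
    n1_mean <- rowMeans(f_inoc)
    ed <- expansion[expansion$treatment == tr, ]
    d_mean <- mean(ed$d)
    for (k in seq_len(nrow(ms))) {
      rep_k <- ms$replicate[[k]]
      n2 <- mutant_frequency(sub, ms$sample_id[[k]])
      n1 <- if (pair_inoculum) f_inoc[, min(k, ncol(f_inoc))] else n1_mean
      d_k <- if (per_replicate_d && rep_k %in% ed$replicate) {
        ed$d[match(rep_k, ed$replicate)]
      } else {
        d_mean
      }
      if (!is.finite(d_k)) {
        abort(paste0("no expansion factor for treatment ", tr))
      }
      out[[length(out) + 1]] <- tibble(
        gene_id = sub$gene_id,
        treatment = tr,
        replicate = rep_k,
        N_t1 = unname(n1),
        N_t2 = unname(n2),
        d = d_k,
        W = relative_fitness(n1, n2, d_k)
      )
    }
  }
  bind_rows(out)
}

#' Mean fitness per gene and treatment
#'
#' @param fitness Tibble from [fitness_table()].
#' @return Tibble `gene_id`, `treatment`, `mean_W`, `n_replicates`
#'   (replicates with a defined W). Genes with no defined replicate in a
#'   treatment get `mean_W = NA`.
#' @export
gene_fitness <- function(fitness) {
  fitness %>%
    group_by(.data$gene_id, .data$treatment) %>%
    summarise(
      mean_W = if (any(!is.na(.data$W))) mean(.data$W, na.rm = TRUE)
               else NA_real_,
      n_replicates = sum(!is.na(.data$W)),
      .groups = "drop"
    )
}
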