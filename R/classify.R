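#' Load an ecological-mode annotation
#'
#' Reads a curated mapping from gene id to protein name, functional label
#' and ecological interaction mode. The package ships a curated annotation
#' for the *Ruegeria pomeroyi* DSS-3 phycosphere mutant set
#' (`rpom_mode_annotation.tsv`), covering the four interaction modes
#' (competition, crossfeeding, chemically mediated, altered environment)
#' together with the published per-contrast fitness log2 fold-changes;
#' user-supplied mappings with the same columns are accepted.
#'
#' @param path Path to a TSV with columns `gene_id`, `protein_name`,
#'   `function_label`, `mode` (extra columns are kept). Defaults to the
#'   packaged annotation.
#' @return Tibble; `mode` validated against the closed set.
#' @export
read_mode_annotation <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rpom_mode_annotation.tsv",
                                package = "phycofit", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "")
  req <- c("gene_id", "protein_name", "function_label", "mode")
  if (!all(req %in% names(df))) {
    abort(paste0("mode annotation must have columns: ",
                 paste(req, collapse = ", ")))
  }
  bad <- setdiff(unique(df$mode), phycofit_modes())
  if (length(bad) > 0) {
    abort(paste0("unknown mode(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) abort("one record per gene required")
  as_tibble(df)
}

#' The closed set of ecological interaction modes
#'
#' Four phenomenological modes of bacterial interaction in the phycosphere
#' (competition for resources, crossfeeding of released metabolites,
#' chemically mediated interactions via secondary metabolites, adaptation
#' to an altered environment), plus the remaining functional bins used for
#' genes outside those four.
#'
#' @return Character vector of valid mode labels.
#' @export
phycofit_modes <- function() {
  c("competition", "crossfeeding", "chemically_mediated",
    "altered_environment", "central_metabolism", "regulation", "mixed",
    "hypothetical")
}

#' Attach interaction modes to significant contrast results
#'
#' Joins mode annotations onto the significant rows of a contrast table
#' and carries the direction of the fitness change. Genes missing from the
#' annotation receive `default_mode`.
#'
#' @param contrasts Tibble from [contrast_fitness()] (needs `gene_id`,
#'   `contrast`, `log2fc`, `significant`).
#' @param annotation Tibble from [read_mode_annotation()].
#' @param default_mode Mode for unannotated genes (default
#'   `"hypothetical"`).
#' @return Tibble of significant rows with `protein_name`,
#'   `function_label`, `mode` and `direction` (`"increase"`/`"decrease"`).
#' @export
annotate_modes <- function(contrasts, annotation = read_mode_annotation(),
                           default_mode = "hypothetical") {
  if (!default_mode %in% phycofit_modes()) {
    abort("default_mode must be one of phycofit_modes()")
  }
  sig <- contrasts[contrasts$significant %in% TRUE, , drop = FALSE]
  ann <- annotation[, c("gene_id", "protein_name", "function_label", "mode")]
  out <- left_join(sig, ann, by = "gene_id")
  out$mode[is.na(out$mode)] <- default_mode
  mutate(out, direction = ifelse(.data$log2fc >= 0, "increase", "decrease"))
}

#' Summarise significant genes by interaction mode
#'
#' Counts distinct significant genes per mode and their fraction of all
#' significant genes (a gene significant in several contrasts counts
#' once).
#'
#' @param annotated Tibble from [annotate_modes()].
#' @return Tibble `mode`, `n_significant`, `fraction_of_significant`;
#'   fractions sum to 1.
#' @export
mode_summary <- function(annotated) {
  if (nrow(annotated) == 0) {
    return(tibble(mode = character(0), n_significant = integer(0),
                  fraction_of_significant = numeric(0)))
  }
  genes <- distinct(annotated[, c("gene_id", "mode")])
  out <- genes %>%
    group_by(.data$mode) %>%
    summarise(n_significant = dplyr::n(), .groups = "drop")
  mutate(out,
         fraction_of_significant = .data$n_significant / sum(.data$n_significant))
}

#' Wide per-gene report of significant fitness changes
#'
#' One row per gene with one column per contrast; a cell holds the log2
#' fold-change (rounded to `digits` significant figures, matching the
#' two-figure style of printed fitness tables) when the change is
#' significant and is blank otherwise.
#'
#' @param contrasts Tibble from [contrast_fitness()].
#' @param digits Significant figures for display (default 2).
#' @return Tibble `gene_id` plus one character column per contrast.
#' @export
emit_table <- function(contrasts, digits = 2) {
  contrast_levels <- unique(contrasts$contrast)
  sig <- contrasts[contrasts$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- tibble(gene_id = character(0))
    for (cl in contrast_levels) out[[cl]] <- character(0)
    return(out)
  }
  sig <- mutate(sig, cell = formatC(signif(.data$log2fc, digits),
                                    format = "fg"))
  wide <- tidyr::pivot_wider(
    sig[, c("gene_id", "contrast", "cell")],
    names_from = "contrast", values_from = "cell", values_fill = ""
  )
  for (cl in setdiff(contrast_levels, names(wide))) wide[[cl]] <- ""
  wide[, c("gene_id", contrast_levels)]
}

#' Parse a wide report back to (gene, contrast, value) triples
#'
#' Inverse of [emit_table()]: blank cells are dropped.
#'
#' @param report Tibble as produced by [emit_table()].
#' @return Tibble `gene_id`, `contrast`, `log2fc` (numeric).
#' @export
parse_report <- function(report) {
  long <- tidyr::pivot_longer(report, -"gene_id",
                              names_to = "contrast", values_to = "cell")
  long <- long[!is.na(long$cell) & long$cell != "", , drop = FALSE]
  tibble(gene_id = long$gene_id, contrast = long$contrast,
         log2fc = as.numeric(long$cell))
}
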