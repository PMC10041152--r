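#' Read a gene annotation as a tibble of gene models
#'
#' Accepts either GFF3 (gene/CDS features, parsed with rtracklayer) or a
#' headered TSV with columns `gene_id`, `replicon_id`, `start`, `end`,
#' `strand` (and optionally `product`). Coordinates are 1-based inclusive in
#' both dialects and are kept that way internally.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gff3"`.
#' @param feature_type For GFF3, which feature types to keep
#'   (default `c("gene", "CDS")`; whichever is present is used, genes first).
#' @return Tibble with columns `gene_id`, `replicon_id`, `start`, `end`,
#'   `strand`, `product`.
#' @export
read_annotation <- function(path, format = c("tsv", "gff3"),
                            feature_type = c("gene", "CDS")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
    req <- c("gene_id", "replicon_id", "start", "end", "strand")
    if (!all(req %in% names(df))) {
      abort(paste0("annotation TSV must have columns: ",
                   paste(req, collapse = ", ")))
    }
    if (!"product" %in% names(df)) df$product <- NA_character_
    genes <- tibble(
      gene_id = as.character(df$gene_id),
      replicon_id = as.character(df$replicon_id),
      start = as.numeric(df$start),
      end = as.numeric(df$end),
      strand = as.character(df$strand),
      product = as.character(df$product)
    )
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% feature_type
    gr <- gr[keep]
    types_present <- intersect(feature_type, unique(as.character(gr$type)))
    if (length(types_present) == 0) {
      abort("no gene/CDS features found in GFF3")
    }
    gr <- gr[as.character(gr$type) == types_present[[1]]]
    ids <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag)
           else as.character(gr$ID)
    prod <- if (!is.null(gr$product)) as.character(gr$product)
            else NA_character_
    genes <- tibble(
      gene_id = ids,
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      start = as.numeric(GenomicRanges::start(gr)),
      end = as.numeric(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      product = prod
    )
  }
  validate_annotation(genes)
  genes
}

validate_annotation <- function(genes) {
  if (any(is.na(genes$gene_id)) || anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)]
    abort(paste0("gene_id must be unique; duplicated: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- genes$start > genes$end
  if (any(bad)) {
    abort(paste0("start > end for gene(s): ",
                 paste(genes$gene_id[bad], collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  invisible(genes)
}

#' Read sample metadata
#'
#' Headered TSV with columns `sample_id`, `treatment`, `replicate`,
#' `timepoint`. Inoculum aliquots carry treatment `"inoculum"` and timepoint
#' `"t1"`; all grown samples are `"t2"`.
#'
#' @param path Path to the metadata TSV.
#' @return Validated tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "treatment", "replicate", "timepoint")
  if (!all(req %in% names(df))) {
    abort(paste0("metadata TSV must have columns: ", paste(req, collapse = ", ")))
  }
  meta <- tibble(
    sample_id = as.character(df$sample_id),
    treatment = as.character(df$treatment),
    replicate = as.integer(df$replicate),
    timepoint = as.character(df$timepoint)
  )
  validate_metadata(meta)
  meta
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id)) abort("sample_id must be unique")
  if (!all(meta$timepoint %in% c("t1", "t2"))) {
    abort("timepoint must be 't1' or 't2'")
  }
  inoc <- meta$treatment == "inoculum"
  if (any(inoc != (meta$timepoint == "t1"))) {
    abort("inoculum samples (and only those) must be timepoint t1")
  }
  key <- paste(meta$treatment, meta$replicate, meta$timepoint)
  if (anyDuplicated(key)) {
    abort("each (treatment, replicate, timepoint) must be unique")
  }
  invisible(meta)
}

#' Read a cell-abundance table
#'
#' Headered TSV with columns `treatment`, `replicate`, `day`,
#' `total_bacteria` (cells/mL, flow cytometry) and one `cfu_<species>`
#' column per enumerated species (CFU/mL), e.g. `cfu_Rp`, `cfu_V`, `cfu_M`.
#'
#' @param path Path to the TSV.
#' @return Tibble with those columns; abundances validated non-negative.
#' @export
read_cell_abundance <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  req <- c("treatment", "replicate", "day", "total_bacteria")
  if (!all(req %in% names(df))) {
    abort(paste0("cell-abundance TSV must have columns: ",
                 paste(req, collapse = ", ")))
  }
  cfu_cols <- grep("^cfu_", names(df), value = TRUE)
  if (length(cfu_cols) == 0) abort("need at least one cfu_<species> column")
  num_cols <- c("day", "total_bacteria", cfu_cols)
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  vals <- unlist(df[, c("total_bacteria", cfu_cols)])
  if (any(vals < 0, na.rm = TRUE)) abort("abundances must be non-negative")
  as_tibble(df)
}
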