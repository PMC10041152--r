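#' Trim transposon-genome junction reads
#'
#' A sequencing read that spans the transposon-genome junction carries the
#' end of the transposon followed by genomic sequence. If the junction motif
#' (the transposon's terminal sequence) starts within the first
#' `search_window` bases of the read, the genomic fragment immediately
#' following the motif is returned, truncated to `keep_length` bases (fewer
#' when the read ends first; at least one base must remain). Reads without a
#' junction in the window yield `NA`.
#'
#' Matching is exact and the first occurrence of the motif is used: the
#' junction is the transposon/genome boundary nearest the read start.
#'
#' @param reads Character vector of reads (alphabet A, C, G, T, N).
#' @param motif Junction motif; default is the Tn5 mosaic-end sequence
#'   used for this mutant library.
#' @param search_window Motif must start within this many bases (1-based).
#' @param keep_length Number of genomic bases to keep after the motif.
#' @return Character vector of trimmed genomic fragments; `NA` where no
#'   junction was found.
#' @export
#' @examples
#' trim_junction_read(paste0("ACGTACGTAC", "AGATGTGTATAAGAGACAG",
#'                           strrep("G", 30)))
trim_junction_read <- function(reads,
                               motif = "AGATGTGTATAAGAGACAG",
                               search_window = 60L,
                               keep_length = 22L) {
  if (length(reads) == 0) return(character(0))
  if (any(is.na(reads)) || any(nchar(reads) == 0)) {
    abort("reads must be non-empty sequences")
  }
  if (nchar(motif) == 0) abort("motif must be non-empty")
  hit <- regexpr(motif, reads, fixed = TRUE)
  start <- as.integer(hit)
  out <- rep(NA_character_, length(reads))
  ok <- start >= 1L & start <= search_window
  if (any(ok)) {
    from <- start[ok] + nchar(motif)
    to <- pmin(from + keep_length - 1L, nchar(reads[ok]))
    frag <- substr(reads[ok], from, to)
    frag[nchar(frag) < 1L] <- NA_character_
    out[ok] <- frag
  }
  out
}

#' Trim a FASTQ file of junction reads to genomic fragments
#'
#' Batch interface over [trim_junction_read()]: reads a (plain-text) FASTQ,
#' trims each read, and writes the retained genomic fragments as FASTA.
#'
#' @param fastq_path Input FASTQ.
#' @param out_path Output FASTA of trimmed fragments.
#' @inheritParams trim_junction_read
#' @return Tibble with `n_reads`, `n_trimmed`, `fraction_trimmed`.
#' @export
trim_fastq <- function(fastq_path, out_path,
                       motif = "AGATGTGTATAAGAGACAG",
                       search_window = 60L, keep_length = 22L) {
  seqs <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  trimmed <- trim_junction_read(as.character(seqs), motif = motif,
                                search_window = search_window,
                                keep_length = keep_length)
  keep <- !is.na(trimmed)
  out <- Biostrings::DNAStringSet(trimmed[keep])
  names(out) <- names(seqs)[keep]
  Biostrings::writeXStringSet(out, out_path, format = "fasta")
  tibble(
    n_reads = length(seqs),
    n_trimmed = sum(keep),
    fraction_trimmed = if (length(seqs) > 0) sum(keep) / length(seqs) else NA_real_
  )
}
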