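#' Read a wig track of per-site insertion counts
#'
#' Parses a UCSC wiggle file in either `variableStep` or `fixedStep` dialect.
#' Each data line becomes one record; `track` and comment lines are ignored.
#' Declaration lines (`variableStep chrom=...` / `fixedStep chrom=... start=...
#' step=...`) set the replicon for the records that follow.
#'
#' @param path Path to a wig file.
#' @return A tibble with columns `replicon_id`, `position` (1-based) and
#'   `count`, in file order.
#' @details Counts must be non-negative; a negative value or a malformed
#'   declaration line raises an error naming the offending line number.
#' @seealso [write_wig()], [combine_wigs()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".wig")
#' writeLines(c("variableStep chrom=NC_003911", "100 5", "150 12"), f)
#' read_wig(f)
read_wig <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("wig file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  replicon <- rep(NA_character_, length(lines))
  position <- rep(NA_real_, length(lines))
  count <- rep(NA_real_, length(lines))

  cur_chrom <- NA_character_
  mode <- NA_character_
  fixed_pos <- NA_real_
  fixed_step <- NA_real_

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "track")) next
    if (startsWith(ln, "variableStep") || startsWith(ln, "fixedStep")) {
      fields <- strsplit(ln, "[ \t]+")[[1]]
      kv <- fields[-1]
      keys <- sub("=.*", "", kv)
      vals <- sub("^[^=]*=", "", kv)
      if (anyNA(match("chrom", keys)) || any(keys == "")) {
        abort(sprintf("malformed wig declaration on line %d: %s", i, ln))
      }
      cur_chrom <- vals[match("chrom", keys)]
      if (startsWith(ln, "fixedStep")) {
        if (!all(c("start", "step") %in% keys)) {
          abort(sprintf(
            "malformed wig declaration on line %d: fixedStep requires start= and step=",
            i
          ))
        }
        mode <- "fixed"
        fixed_pos <- as.numeric(vals[match("start", keys)])
        fixed_step <- as.numeric(vals[match("step", keys)])
        if (is.na(fixed_pos) || is.na(fixed_step)) {
          abort(sprintf("malformed wig declaration on line %d: %s", i, ln))
        }
      } else {
        mode <- "variable"
      }
      next
    }
    # data line
    if (is.na(mode)) {
      abort(sprintf("wig data before any declaration line (line %d)", i))
    }
    if (mode == "variable") {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      if (length(parts) != 2) {
        abort(sprintf("malformed wig data on line %d: %s", i, ln))
      }
      pos <- as.numeric(parts[[1]])
      val <- as.numeric(parts[[2]])
      if (is.na(pos) || is.na(val)) {
        abort(sprintf("malformed wig data on line %d: %s", i, ln))
      }
    } else {
      val <- as.numeric(ln)
      if (is.na(val)) {
        abort(sprintf("malformed wig data on line %d: %s", i, ln))
      }
      pos <- fixed_pos
      fixed_pos <- fixed_pos + fixed_step
    }
    if (val < 0) {
      abort(sprintf("negative count on line %d: %s", i, ln))
    }
    replicon[[i]] <- cur_chrom
    position[[i]] <- pos
    count[[i]] <- val
  }

  keep <- !is.na(replicon)
  tibble(
    replicon_id = replicon[keep],
    position = position[keep],
    count = count[keep]
  )
}

#' Write per-site insertion counts as a variableStep wig track
#'
#' @param sites Tibble with columns `replicon_id`, `position`, `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(sites, path) {
  stopifnot(all(c("replicon_id", "position", "count") %in% names(sites)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in unique(sites$replicon_id)) {
    sub <- sites[sites$replicon_id == chrom, ]
    writeLines(sprintf("variableStep chrom=%s", chrom), con)
    writeLines(sprintf("%d %s", as.integer(sub$position),
                       format(sub$count, trim = TRUE, scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Combine per-sample wig tracks into a site-by-sample count matrix
#'
#' Rows are the union of all (replicon, position) keys across tracks; a site
#' absent from a track gets count 0 for that sample. Sites whose counts are
#' zero in every sample are dropped (positions with no insertional mutants
#' carry no information about the pool).
#'
#' @param tracks List of per-sample site tibbles as returned by [read_wig()].
#' @param sample_ids Character vector parallel to `tracks`; must be unique.
#' @return A tibble with columns `replicon_id`, `position` and one count
#'   column per sample, ordered by replicon then position.
#' @export
combine_wigs <- function(tracks, sample_ids) {
  if (length(tracks) < 1) abort("need at least one track")
  if (length(sample_ids) != length(tracks)) {
    abort("sample_ids must be parallel to tracks")
  }
  if (anyDuplicated(sample_ids)) abort("sample_ids must be unique")

  long <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    key <- paste(tr$replicon_id, tr$position)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][[1]]
      abort(sprintf(
        "duplicate position within track '%s' (site %s): count is ambiguous",
        sample_ids[[i]], dup
      ))
    }
    tibble(
      replicon_id = tr$replicon_id, position = tr$position,
      sample_id = sample_ids[[i]], count = tr$count
    )
  })
  long <- bind_rows(long)

  wide <- tidyr::pivot_wider(
    long,
    id_cols = c("replicon_id", "position"),
    names_from = "sample_id", values_from = "count",
    values_fill = 0
  )
  # restore requested sample order and drop all-zero sites
  wide <- wide[, c("replicon_id", "position", sample_ids)]
  totals <- rowSums(as.matrix(wide[, sample_ids, drop = FALSE]))
  wide <- wide[totals > 0, , drop = FALSE]
  arrange(wide, .data$replicon_id, .data$position)
}
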