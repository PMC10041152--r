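#' Proportion of a species in the enumerated community
#'
#' @param species_cfu Named numeric vector of CFU/mL per species
#'   (e.g. `c(Rp = 8e5, V = 2e5)`).
#' @param species Which species' proportion to return.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' species_proportion(c(Rp = 8e5, V = 2e5), "Rp")
species_proportion <- function(species_cfu, species) {
  total <- sum(species_cfu)
  if (!is.finite(total) || total <= 0) abort("total CFU must be > 0")
  if (!species %in% names(species_cfu)) {
    abort(paste0("species '", species, "' not in CFU record"))
  }
  unname(species_cfu[[species]] / total)
}

#' Expansion factor of the focal-species mutant pool
#'
#' The expansion factor `d` is the fold change of the focal-species pool
#' between the two sequenced timepoints, estimated as flow-cytometry total
#' cell counts apportioned by CFU-based species proportions:
#' `d = (total2 * prop2) / (total1 * prop1)`. `generations = log2(d)` is
#' the number of population doublings.
#'
#' @param t1,t2 Lists (or one-row data frames) with `total_bacteria`
#'   (cells/mL) and `species_cfu` (named CFU vector). For single-species
#'   cultures the proportion is 1.
#' @param species Focal species (default `"Rp"`).
#' @return List with `d` and `generations`.
#' @export
#' @examples
#' expansion_factor(
#'   t1 = list(total_bacteria = 1e5, species_cfu = c(Rp = 1e5)),
#'   t2 = list(total_bacteria = 4.5e6, species_cfu = c(Rp = 4.5e6))
#' )
expansion_factor <- function(t1, t2, species = "Rp") {
  p1 <- species_proportion(t1$species_cfu, species)
  p2 <- species_proportion(t2$species_cfu, species)
  if (t1$total_bacteria <= 0 || t2$total_bacteria < 0) {
    abort("total_bacteria must be positive at t1 and non-negative at t2")
  }
  focal1 <- t1$total_bacteria * p1
  if (focal1 <= 0) abort("focal species absent at t1; d undefined")
  d <- (t2$total_bacteria * p2) / focal1
  list(d = d, generations = log2(d))
}

#' Per-replicate expansion factors from a cell-abundance table
#'
#' Applies [expansion_factor()] to every (treatment, replicate) pair in a
#' cell-abundance table, using the records at `t1_day` and `t2_day`
#' (endpoint proportions, no interpolation).
#'
#' @param cell_abundance Tibble as from [read_cell_abundance()]: columns
#'   `treatment`, `replicate`, `day`, `total_bacteria`, `cfu_<species>...`.
#' @param species Focal species (matched against the `cfu_` columns).
#' @param t1_day,t2_day Days delimiting the growth window (defaults 0, 8).
#' @return Tibble `treatment`, `replicate`, `d`, `generations`.
#' @export
expansion_table <- function(cell_abundance, species = "Rp",
                            t1_day = 0, t2_day = 8) {
  cfu_cols <- grep("^cfu_", names(cell_abundance), value = TRUE)
  sp_names <- sub("^cfu_", "", cfu_cols)
  as_record <- function(row) {
    cfu <- as.numeric(row[1, cfu_cols])
    names(cfu) <- sp_names
    cfu <- cfu[!is.na(cfu)]
    list(total_bacteria = row$total_bacteria[[1]], species_cfu = cfu)
  }
  keys <- distinct(cell_abundance[, c("treatment", "replicate")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    tr <- keys$treatment[[i]]
    rp <- keys$replicate[[i]]
    sub <- cell_abundance[cell_abundance$treatment == tr &
                          cell_abundance$replicate == rp, ]
    r1 <- sub[sub$day == t1_day, ]
    r2 <- sub[sub$day == t2_day, ]
    if (nrow(r1) != 1 || nrow(r2) != 1) {
      abort(sprintf("need exactly one record at day %s and day %s for %s rep %s",
                    t1_day, t2_day, tr, rp))
    }
    ef <- expansion_factor(as_record(r1), as_record(r2), species)
    tibble(treatment = tr, replicate = rp, d = ef$d,
           generations = ef$generations)
  })
  bind_rows(res)
}
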