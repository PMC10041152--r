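#' Configuration for a synthetic mutant-pool experiment
#'
#' Defaults emulate the study conditions of a pooled transposon-mutant
#' competition in a model phycosphere: ~15 insertion sites per gene, four
#' treatments (single-bacterium reference `Rp` plus three multispecies
#' communities) with four replicate flasks each and four sequenced
#' inoculum aliquots, pool expansions of 2^6.4 generations-equivalent in
#' the reference down to 2^4.4 in the three-species community (the two
#' intermediate treatments interpolated at 2^5.4), and multinomial
#' sequencing at 2e6 reads per sample.
#'
#' @param n_genes Number of genes on the synthetic replicon.
#' @param mean_sites_per_gene Poisson mean of insertion sites per gene.
#' @param gene_length Gene length in bp.
#' @param intergenic_length Gap between consecutive genes in bp.
#' @param intergenic_fraction Expected intergenic sites as a fraction of
#'   genic sites.
#' @param n_replicates Replicate flasks per treatment.
#' @param n_aliquots Sequenced inoculum aliquots.
#' @param treatments Treatment names; the first is the single-species
#'   reference.
#' @param generations Named vector of pool doublings per treatment
#'   (`d = 2^generations`).
#' @param effects Optional tibble `gene_id`, `treatment`, `multiplier`:
#'   the mutant's per-cell growth-rate multiplier relative to the pool
#'   (1 = neutral, 0 = no growth, 0.5 = half rate). Unlisted pairs are
#'   neutral. Effects are parameterized as rate multipliers rather than
#'   target W because W depends on depth and d; the true W implied by a
#'   multiplier is computed in closed form into the truth table.
#' @param read_depth Total reads per sample.
#' @param dispersion Dirichlet-multinomial overdispersion (0 = pure
#'   multinomial).
#' @param site_lognormal_sd sdlog of the lognormal jitter on initial
#'   per-mutant abundances.
#' @param psi Pseudocount used for the truth-table log2 fold-changes.
#' @param seed Integer seed; the whole simulation is deterministic
#'   given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500,
                       mean_sites_per_gene = 15,
                       gene_length = 900,
                       intergenic_length = 100,
                       intergenic_fraction = 0.1,
                       n_replicates = 4,
                       n_aliquots = 4,
                       treatments = c("Rp", "Rp+V", "Rp+M", "Rp+V+M"),
                       generations = c("Rp" = 6.4, "Rp+V" = 5.4,
                                       "Rp+M" = 5.4, "Rp+V+M" = 4.4),
                       effects = NULL,
                       read_depth = 2e6,
                       dispersion = 0,
                       site_lognormal_sd = 1,
                       psi = 0.01,
                       seed = 1L) {
  if (!all(treatments %in% names(generations))) {
    abort("generations must name every treatment")
  }
  if (!is.null(effects)) {
    req <- c("gene_id", "treatment", "multiplier")
    if (!all(req %in% names(effects))) {
      abort("effects needs columns gene_id, treatment, multiplier")
    }
    if (!all(effects$treatment %in% treatments)) {
      abort("effects reference unknown treatments")
    }
    if (any(effects$multiplier < 0)) abort("multipliers must be >= 0")
  }
  structure(
    list(
      n_genes = n_genes, mean_sites_per_gene = mean_sites_per_gene,
      gene_length = gene_length, intergenic_length = intergenic_length,
      intergenic_fraction = intergenic_fraction,
      n_replicates = n_replicates, n_aliquots = n_aliquots,
      treatments = treatments, generations = generations,
      effects = effects, read_depth = read_depth, dispersion = dispersion,
      site_lognormal_sd = site_lognormal_sd, psi = psi,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a transposon mutant library
#'
#' Tiles `n_genes` genes along one synthetic replicon, draws per-gene site
#' counts from a Poisson around `mean_sites_per_gene`, places sites
#' uniformly (without replacement) within each gene, and adds intergenic
#' sites at the configured fraction. Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `annotation` (gene-model tibble) and `sites`
#'   (tibble `replicon_id`, `position`, `gene_id`; intergenic sites have
#'   `gene_id = NA`).
#' @export
simulate_library <- function(config) {
  withr::with_seed(config$seed, {
    L <- config$gene_length
    S <- config$intergenic_length
    unit <- L + S
    starts <- (seq_len(config$n_genes) - 1) * unit + S + 1
    annotation <- tibble(
      gene_id = sprintf("SG%05d", seq_len(config$n_genes)),
      replicon_id = "synth_chr1",
      start = starts,
      end = starts + L - 1,
      strand = rep_len(c("+", "-"), config$n_genes),
      product = "simulated protein"
    )
    n_sites <- rpois(config$n_genes, config$mean_sites_per_gene)
    pos <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      k <- min(n_sites[[i]], L)
      pos[[i]] <- if (k > 0) sort(sample.int(L, k)) + starts[[i]] - 1
                  else numeric(0)
    }
    genic <- tibble(
      replicon_id = "synth_chr1",
      position = unlist(pos),
      gene_id = rep(annotation$gene_id, lengths(pos))
    )
    n_inter <- rpois(1, config$intergenic_fraction *
                        config$n_genes * config$mean_sites_per_gene)
    inter <- tibble(replicon_id = character(0), position = numeric(0),
                    gene_id = character(0))
    if (n_inter > 0 && S > 0) {
      gap <- sample.int(config$n_genes, n_inter, replace = TRUE)
      off <- sample.int(S, n_inter, replace = TRUE)
      p <- (gap - 1) * unit + off
      p <- unique(p)
      inter <- tibble(replicon_id = "synth_chr1", position = p,
                      gene_id = NA_character_)
    }
    sites <- bind_rows(genic, inter)
    sites <- arrange(sites[!duplicated(sites$position), ], .data$position)
    list(annotation = annotation, sites = sites)
  })
}

#' Simulate a full pooled-competition experiment
#'
#' Growth is deterministic-exponential: a mutant in gene *g* multiplies by
#' `d^m(g, T)` over the experiment while the pool multiplies by roughly
#' `d = 2^generations[T]`; noise enters only through the lognormal jitter
#' on initial abundances and the (Dirichlet-)multinomial read sampling.
#' Inoculum aliquots are sequenced from the shared starting pool.
#' Cell-abundance records are emitted consistent with the realized pool
#' expansion, so growth accounting recovers `d` exactly.
#'
#' @param config A [sim_config()].
#' @param library Optional library from [simulate_library()]; generated
#'   from `config` when omitted.
#' @return A `phycofit_sim` list: `config`, `annotation`, `sites` (site
#'   catalogue), `counts` (site-by-sample tibble in [combine_wigs()]
#'   layout), `metadata`, `cell_abundance`, `truth` (tibble `gene_id`,
#'   `treatment`, `multiplier`, `true_W`, `true_log2fc`), `realized_d`.
#' @export
simulate_experiment <- function(config, library = NULL) {
  library <- library %||% simulate_library(config)
  sites <- library$sites
  n_sites <- nrow(sites)
  if (n_sites == 0) abort("library has no insertion sites")
  ref <- config$treatments[[1]]

  withr::with_seed(config$seed + 1L, {
    a1 <- rlnorm(n_sites, meanlog = 0, sdlog = config$site_lognormal_sd)
    f1 <- a1 / sum(a1)

    draw_reads <- function(freq) {
      p <- freq
      if (config$dispersion > 0) {
        g <- rgamma(length(freq), shape = freq / config$dispersion)
        p <- if (sum(g) > 0) g / sum(g) else freq
      }
      as.numeric(rmultinom(1, size = config$read_depth, prob = p))
    }

    counts <- tibble(replicon_id = sites$replicon_id,
                     position = sites$position)
    meta <- list()
    for (j in seq_len(config$n_aliquots)) {
      sid <- sprintf("inoc_%d", j)
      counts[[sid]] <- draw_reads(f1)
      meta[[length(meta) + 1]] <- tibble(
        sample_id = sid, treatment = "inoculum", replicate = j,
        timepoint = "t1"
      )
    }

    mult_of <- function(tr) {
      m <- rep(1, n_sites)
      if (!is.null(config$effects)) {
        eff <- config$effects[config$effects$treatment == tr, ]
        idx <- match(sites$gene_id, eff$gene_id)
        hit <- !is.na(idx)
        m[hit] <- eff$multiplier[idx[hit]]
      }
      m
    }

    realized <- list()
    truth <- list()
    cells <- list()
    for (tr in config$treatments) {
      d_t <- 2^config$generations[[tr]]
      m <- mult_of(tr)
      a2 <- a1 * d_t^m
      f2 <- a2 / sum(a2)
      D <- sum(a2) / sum(a1)
      realized[[length(realized) + 1]] <- tibble(treatment = tr, d = D)

      tag <- gsub("[^A-Za-z0-9]", "", tr)
      for (r in seq_len(config$n_replicates)) {
        sid <- sprintf("%s_%d", tag, r)
        counts[[sid]] <- draw_reads(f2)
        meta[[length(meta) + 1]] <- tibble(
          sample_id = sid, treatment = tr, replicate = r, timepoint = "t2"
        )
        cells[[length(cells) + 1]] <- sim_cell_abundance(tr, r, D)
      }

      # closed-form per-gene truth: mutant expansion d^m, rest-of-pool
      # expansion excluding the gene
      genic <- !is.na(sites$gene_id)
      A1g <- tapply(a1[genic], sites$gene_id[genic], sum)
      A2g <- tapply(a2[genic], sites$gene_id[genic], sum)
      gid <- names(A1g)
      D_rest <- (sum(a2) - A2g) / (sum(a1) - A1g)
      mg <- rep(1, length(gid))
      if (!is.null(config$effects)) {
        eff <- config$effects[config$effects$treatment == tr, ]
        idx <- match(gid, eff$gene_id)
        mg[!is.na(idx)] <- eff$multiplier[idx[!is.na(idx)]]
      }
      truth[[length(truth) + 1]] <- tibble(
        gene_id = gid, treatment = tr, multiplier = mg,
        true_W = as.numeric(log(d_t^mg + 1) / log(D_rest + 1))
      )
    }

    truth <- bind_rows(truth)
    ref_w <- truth[truth$treatment == ref, c("gene_id", "true_W")]
    ref_w <- rename(ref_w, ref_W = "true_W")
    truth <- left_join(truth, ref_w, by = "gene_id")
    truth$true_log2fc <- log2((truth$true_W + config$psi) /
                              (truth$ref_W + config$psi))
    truth$ref_W <- NULL

    structure(
      list(
        config = config,
        annotation = library$annotation,
        sites = sites,
        counts = counts,
        metadata = bind_rows(meta),
        cell_abundance = bind_rows(cells),
        truth = truth,
        realized_d = bind_rows(realized)
      ),
      class = "phycofit_sim"
    )
  })
}

# Flow-cytometry totals and CFU proportions consistent with the realized
# focal-pool expansion D; companion species follow the qualitative course
# of the study communities (Vibrio crashes, Marinobacter doubles).
sim_cell_abundance <- function(treatment, replicate, D) {
  rp1 <- 1e5
  rp2 <- rp1 * D
  v <- grepl("V", treatment)
  m <- grepl("M", treatment)
  v1 <- if (v) 2e5 else NA_real_; v2 <- if (v) 50 else NA_real_
  m1 <- if (m) 1e5 else NA_real_; m2 <- if (m) 2e5 else NA_real_
  plate_eff <- 0.1  # CFU per cell; proportions are what matter
  tibble(
    treatment = treatment,
    replicate = replicate,
    day = c(0, 8),
    total_bacteria = c(sum(rp1, v1, m1, na.rm = TRUE),
                       sum(rp2, v2, m2, na.rm = TRUE)),
    cfu_Rp = c(rp1, rp2) * plate_eff,
    cfu_V = c(v1, v2) * plate_eff,
    cfu_M = c(m1, m2) * plate_eff
  )
}

#' @export
print.phycofit_sim <- function(x, ...) {
  cat(sprintf(
    "phycofit_sim: %d genes, %d sites, %d samples, depth %g (seed %d)\n",
    nrow(x$annotation), nrow(x$sites), nrow(x$metadata),
    x$config$read_depth, x$config$seed
  ))
  invisible(x)
}

#' Write a simulated experiment in the pipeline's external formats
#'
#' Emits exactly what the io stage reads: one variableStep wig track per
#' sample, annotation, metadata, cell-abundance and truth TSVs.
#'
#' @param sim A `phycofit_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in sim$metadata$sample_id) {
    tr <- tibble(replicon_id = sim$counts$replicon_id,
                 position = sim$counts$position,
                 count = sim$counts[[sid]])
    write_wig(tr[tr$count > 0, ], file.path(dir, paste0(sid, ".wig")))
  }
  wt <- function(df, f) {
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(sim$annotation, "annotation.tsv")
  wt(sim$metadata, "metadata.tsv")
  wt(sim$cell_abundance, "cell_abundance.tsv")
  wt(sim$truth, "truth.tsv")
  invisible(dir)
}
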