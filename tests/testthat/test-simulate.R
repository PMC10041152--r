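test_that("simulated libraries are deterministic and match the site budget", {
  cfg <- sim_config(n_genes = 100, seed = 31)
  lib1 <- simulate_library(cfg)
  lib2 <- simulate_library(cfg)
  expect_identical(lib1, lib2)
  total_genic <- sum(!is.na(lib1$sites$gene_id))
  expect_lt(abs(total_genic - 1500), 4 * sqrt(1500))  # Poisson expectation
  expect_equal(nrow(lib1$annotation), 100)
  # all genic sites lie within their gene
  sub <- lib1$sites[!is.na(lib1$sites$gene_id), ]
  m <- match(sub$gene_id, lib1$annotation$gene_id)
  expect_true(all(sub$position >= lib1$annotation$start[m] &
                  sub$position <= lib1$annotation$end[m]))

  none <- simulate_library(sim_config(n_genes = 10, mean_sites_per_gene = 0,
                                      intergenic_fraction = 0, seed = 1))
  expect_equal(sum(!is.na(none$sites$gene_id)), 0)
})

test_that("simulated experiments conserve frequencies and emit readable formats", {
  cfg <- sim_config(n_genes = 40, read_depth = 1e5, seed = 37)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$metadata), 4 + 4 * 4)
  expect_equal(colSums(as.matrix(sim$counts[, sim$metadata$sample_id])),
               setNames(rep(1e5, 20), sim$metadata$sample_id))
  # growth accounting on the emitted cell records recovers the realized d
  et <- expansion_table(sim$cell_abundance)
  merged <- dplyr::inner_join(et, sim$realized_d, by = "treatment")
  expect_equal(merged$d.x, merged$d.y, tolerance = 1e-9)

  dir <- tempfile()
  write_simulation(sim, dir)
  w <- read_wig(file.path(dir, "inoc_1.wig"))
  expect_gt(nrow(w), 0)
  keep <- sim$counts$inoc_1 > 0
  expect_equal(w$position, sim$counts$position[keep])
  expect_equal(w$count, sim$counts$inoc_1[keep])
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  expect_equal(nrow(ann), 40)
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(meta), 20)
  ca <- read_cell_abundance(file.path(dir, "cell_abundance.tsv"))
  expect_equal(nrow(ca), 2 * 4 * 4)
})

test_that("an all-neutral pool recovers W near one through the pipeline", {
  cfg <- sim_config(n_genes = 100, read_depth = 5e5, seed = 41)
  sim <- simulate_experiment(cfg)
  res <- run_sim_pipeline(sim)
  gf <- res$gene_fitness
  expect_true(all(abs(gf$mean_W - 1) < 0.2))
  expect_lt(abs(mean(gf$mean_W) - 1), 0.05)
  expect_true(all(abs(sim$truth$true_W - 1) < 1e-9))
})

test_that("a knockout effect in one treatment collapses fitness there only", {
  eff <- tibble::tibble(gene_id = "SG00005", treatment = "Rp+V",
                        multiplier = 0)
  cfg <- sim_config(n_genes = 80, read_depth = 5e5, effects = eff, seed = 43)
  sim <- simulate_experiment(cfg)
  res <- run_sim_pipeline(sim)
  gf <- res$gene_fitness
  w_hit <- gf$mean_W[gf$gene_id == "SG00005" & gf$treatment == "Rp+V"]
  w_ref <- gf$mean_W[gf$gene_id == "SG00005" & gf$treatment == "Rp"]
  # zero growth against a pool expanding ~2^5.4-fold
  d <- 2^5.4
  expect_equal(w_hit, log(2) / log(d + 1), tolerance = 0.05)
  expect_lt(w_hit, 0.3)
  expect_equal(w_ref, 1, tolerance = 0.05)
  # truth table carries the same closed form
  tw <- sim$truth$true_W[sim$truth$gene_id == "SG00005" &
                         sim$truth$treatment == "Rp+V"]
  expect_equal(w_hit, tw, tolerance = 0.05)
  # contrast flags the right direction
  ct <- res$contrasts
  row <- ct[ct$gene_id == "SG00005" & ct$treatment == "Rp+V", ]
  expect_lt(row$log2fc, -1)
  expect_equal(row$p_raw, 2 / 70)
})

test_that("estimated W is monotone in the true growth-rate multiplier", {
  grid <- c(0.25, 0.5, 1, 1.5)
  genes <- sprintf("SG%05d", 1:120)
  eff <- tidyr::expand_grid(
    gene_id = genes,
    treatment = c("Rp+V", "Rp+M", "Rp+V+M")
  )
  eff$multiplier <- rep(rep(grid, each = 30), times = 3)
  cfg <- sim_config(n_genes = 120, read_depth = 1e6, effects = eff, seed = 47)
  sim <- simulate_experiment(cfg)
  res <- run_sim_pipeline(sim)
  gf <- res$gene_fitness[res$gene_fitness$treatment == "Rp+V+M", ]
  gf$mult <- eff$multiplier[match(paste(gf$gene_id, "Rp+V+M"),
                                  paste(eff$gene_id, eff$treatment))]
  grp <- tapply(gf$mean_W, gf$mult, mean)
  expect_true(all(diff(grp[order(as.numeric(names(grp)))]) > 0))
  # rank agreement between truth and estimate
  tr <- sim$truth[sim$truth$treatment == "Rp+V+M", ]
  j <- dplyr::inner_join(gf, tr, by = "gene_id")
  expect_gt(cor(j$mean_W, j$true_W, method = "spearman"), 0.9)
})

test_that("sparse-effect experiments keep the empirical FDR within bounds", {
  # 5% of genes carry strong knockdown effects. Relative fitness is
  # compositional: when those mutants crash, every other mutant's
  # frequency share - and hence its true W relative to the pool -
  # genuinely rises, and the truth table records that shift. A discovery
  # is therefore false when it contradicts the ground-truth fold-change
  # (wrong sign, or no true change at all), counted over repeats.
  fp <- 0L; disc <- 0L
  for (k in 1:10) {
    genes <- sprintf("SG%05d", 1:100)
    hit <- genes[1:5]
    eff <- tidyr::expand_grid(gene_id = hit,
                              treatment = c("Rp+V", "Rp+M", "Rp+V+M"))
    eff$multiplier <- 0.25
    cfg <- sim_config(n_genes = 100, read_depth = 2e5, effects = eff,
                      seed = 500 + k)
    res <- run_sim_pipeline(simulate_experiment(cfg))
    sig <- dplyr::inner_join(
      res$contrasts[res$contrasts$significant, ],
      res$truth[, c("gene_id", "treatment", "true_log2fc")],
      by = c("gene_id", "treatment")
    )
    disc <- disc + nrow(sig)
    fp <- fp + sum(abs(sig$true_log2fc) < 1e-9 |
                     sign(sig$log2fc) != sign(sig$true_log2fc))
  }
  fdr <- if (disc > 0) fp / disc else 0
  expect_lte(fdr, 0.10)
})
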