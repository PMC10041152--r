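test_that("the pseudocounted log2 fold-change matches direct arithmetic", {
  expect_equal(log2_fold_change(1, 1), 0)
  expect_equal(log2_fold_change(0, 0), 0)  # psi/psi
  expect_equal(log2_fold_change(1.99, 0.99, 0.01), 1)
  expect_error(log2_fold_change(1, 1, psi = 0), "psi")
  expect_error(log2_fold_change(-1, 1), "non-negative")
})

test_that("degenerate and tiny randomization tests match exact enumeration", {
  expect_equal(randomization_test(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)
  expect_equal(randomization_test(c(1, 1), c(2, 2)), 2 / 6)
  # label invariance: shuffling within groups changes nothing (exact branch)
  expect_equal(randomization_test(c(1.3, 0.7, 1.1), c(2.2, 1.8, 2.0)),
               randomization_test(c(0.7, 1.1, 1.3), c(1.8, 2.0, 2.2)))
  # untestable with fewer than two defined values per group
  expect_true(is.na(randomization_test(1, c(1, 2))))
  expect_true(is.na(randomization_test(c(1, NA), c(1, 2))))
})

test_that("the exact branch reproduces an independent enumeration oracle", {
  set.seed(17)
  for (i in 1:20) {
    x <- runif(sample(2:4, 1), 0, 3)
    y <- runif(sample(2:4, 1), 0, 3)
    expect_equal(randomization_test(x, y), perm_brute_force(x, y))
  }
})

test_that("sampled permutation p agrees with enumeration within Monte-Carlo error", {
  set.seed(19)
  for (i in 1:5) {
    x <- runif(4, 0.5, 1.5)
    y <- runif(4, 0.8, 2.0)
    p_exact <- randomization_test(x, y, exact = "always")
    p_samp <- randomization_test(x, y, n_perm = 10000, exact = "never",
                                 seed = 100 + i)
    mc_sd <- sqrt(p_exact * (1 - p_exact) / 10000)
    expect_lt(abs(p_samp - p_exact), 4 * mc_sd + 2e-4)
  }
})

test_that("sampling is reproducible under a seed and leaves the RNG alone", {
  x <- runif(4); y <- runif(4)
  p1 <- randomization_test(x, y, n_perm = 200, exact = "never", seed = 5)
  p2 <- randomization_test(x, y, n_perm = 200, exact = "never", seed = 5)
  expect_equal(p1, p2)
  set.seed(33)
  before <- runif(1)
  set.seed(33)
  invisible(randomization_test(x, y, n_perm = 50, exact = "never"))
  expect_equal(runif(1), before)
})

test_that("bh_adjust equals the hand-computed step-up on worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("bh_adjust matches a brute-force step-up on random vectors", {
  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute_force(p), tolerance = 1e-12)
  }
})

test_that("significance uses a strict threshold on adjusted p", {
  res <- tibble::tibble(p_adj = c(0.049, 0.05, NA))
  out <- call_significance(res, alpha = 0.05)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  empty <- call_significance(tibble::tibble(p_adj = numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("contrast_fitness contrasts each multispecies treatment against the reference", {
  set.seed(29)
  genes <- paste0("g", 1:6)
  mk <- function(tr, w_by_gene) {
    tibble::tibble(
      gene_id = rep(genes, each = 4), treatment = tr,
      replicate = rep(1:4, times = length(genes)),
      N_t1 = 0.01, N_t2 = 0.01, d = 45,
      W = unlist(lapply(w_by_gene, function(w) w + rnorm(4, 0, 0.01)))
    )
  }
  ref_w <- rep(1, 6)
  multi_w <- c(4, 0.2, 1, 1, 1, 1)  # two strong shifts
  fit <- dplyr::bind_rows(mk("Rp", as.list(ref_w)),
                          mk("Rp+V", as.list(multi_w)))
  res <- contrast_fitness(fit, reference = "Rp", seed = 1)
  expect_equal(unique(res$contrast), "Rp+V vs Rp")
  expect_equal(nrow(res), 6)
  shifted <- res[res$gene_id %in% c("g1", "g2"), ]
  expect_true(all(shifted$p_raw == min(res$p_raw)))
  expect_equal(sign(shifted$log2fc), c(1, -1))
  # the minimal exact p for 4-vs-4 groups is 2/70
  expect_equal(min(res$p_raw), 2 / 70)
  # BH is within contrast: adjusted p never below raw
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
})
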