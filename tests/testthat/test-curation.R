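test_that("central windows trim ceil(L(1-f)/2) from each end", {
  g <- tibble::tibble(gene_id = "g", replicon_id = "c", start = 1, end = 100,
                      strand = "+", product = NA)
  w <- central_window(g, 0.9)
  expect_equal(c(w$window_low, w$window_high), c(6, 95))
  # brute force: exactly 90 of the 100 positions fall inside
  inside <- sum((1:100) >= w$window_low & (1:100) <= w$window_high)
  expect_equal(inside, 90)

  g2 <- tibble::tibble(gene_id = "g", replicon_id = "c", start = 11, end = 20,
                       strand = "+", product = NA)
  w2 <- central_window(g2, 0.9)
  expect_equal(c(w2$window_low, w2$window_high), c(12, 19))
  expect_equal(sum((11:20) >= w2$window_low & (11:20) <= w2$window_high), 8)

  w3 <- central_window(g, 1.0)
  expect_equal(c(w3$window_low, w3$window_high), c(1, 100))

  expect_error(central_window(g, 0), "fraction")
  expect_error(central_window(g, 1.2), "fraction")
})

test_that("the central window never admits more than fraction*L positions", {
  set.seed(3)
  for (i in 1:50) {
    s <- sample.int(1000, 1)
    L <- sample.int(300, 1) + 1
    f <- runif(1, 0.3, 1)
    g <- tibble::tibble(gene_id = "g", start = s, end = s + L - 1)
    w <- central_window(g, f)
    inside <- sum((s:(s + L - 1)) >= w$window_low &
                  (s:(s + L - 1)) <= w$window_high)
    expect_lte(inside, f * L)
    expect_equal(inside, L - 2 * ceiling(L * (1 - f) / 2))
  }
})

test_that("assign_sites matches brute-force window membership", {
  set.seed(7)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:8),
    replicon_id = sample(c("chr1", "chr2"), 8, replace = TRUE),
    start = sample.int(2000, 8),
    strand = "+", product = NA
  )
  genes$end <- genes$start + sample.int(400, 8) + 10
  sites <- tibble::tibble(
    replicon_id = sample(c("chr1", "chr2", "chr3"), 120, replace = TRUE),
    position = sample.int(2600, 120),
    s1 = rpois(120, 4)
  )
  sites <- sites[!duplicated(paste(sites$replicon_id, sites$position)), ]
  lib <- assign_sites(sites, genes, 0.9)

  win <- central_window(genes, 0.9)
  expected <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(genes))) {
      if (sites$replicon_id[i] == win$replicon_id[j] &&
          sites$position[i] >= win$window_low[j] &&
          sites$position[i] <= win$window_high[j]) {
        expected[[length(expected) + 1]] <-
          paste(win$gene_id[j], sites$replicon_id[i], sites$position[i])
      }
    }
  }
  got <- paste(lib$assignments$gene_id, lib$assignments$replicon_id,
               lib$assignments$position)
  expect_setequal(got, unlist(expected))
  expect_equal(lib$n_unique_mutants, nrow(sites))
})

test_that("window boundaries are inclusive and overlapping genes both receive a site", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2"),
    replicon_id = "chr1",
    start = c(1, 50), end = c(100, 150),
    strand = "+", product = NA
  )
  w <- central_window(genes, 0.9)
  sites <- tibble::tibble(
    replicon_id = "chr1",
    position = c(w$window_low[1], w$window_high[1], 60),
    s1 = c(1, 1, 1)
  )
  lib <- assign_sites(sites, genes, 0.9)
  # both boundary sites assigned to g1
  expect_true(all(c(w$window_low[1], w$window_high[1]) %in%
                  lib$assignments$position[lib$assignments$gene_id == "g1"]))
  # position 60 sits inside both central windows
  owners <- lib$assignments$gene_id[lib$assignments$position == 60]
  expect_setequal(owners, c("g1", "g2"))
  expect_true(all(lib$assignments$multi_gene[lib$assignments$position == 60]))
  # curated count is over distinct sites, not assignments
  expect_equal(lib$n_curated_mutants, 3)
})

test_that("shrinking the central fraction never increases curated mutants", {
  set.seed(21)
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:10), replicon_id = "chr1",
    start = seq(1, by = 500, length.out = 10),
    strand = "+", product = NA
  )
  genes$end <- genes$start + 399
  sites <- tibble::tibble(
    replicon_id = "chr1",
    position = sample.int(5000, 300),
    s1 = rpois(300, 3)
  )
  fractions <- c(1, 0.9, 0.7, 0.5, 0.3)
  curated <- vapply(fractions, function(f) {
    assign_sites(sites, genes, f)$n_curated_mutants
  }, numeric(1))
  expect_true(all(diff(curated) <= 0))
})

test_that("library_summary counts genes hit and the fraction of the annotation", {
  genes <- toy_annotation()
  sites <- tibble::tibble(
    replicon_id = c("chr1", "chr1", "chr2"),
    position = c(300, 310, 5000),  # two in gA, one outside all windows
    s1 = c(2, 3, 4)
  )
  lib <- assign_sites(sites, genes, 0.9)
  s <- library_summary(lib, genes)
  expect_equal(s$genes_hit, 1)
  expect_equal(s$fraction_hit, 1 / 3)
  expect_equal(s$n_unique_mutants, 3)
  expect_equal(s$n_curated_mutants, 2)

  empty <- assign_sites(
    tibble::tibble(replicon_id = "chrX", position = 1, s1 = 0),
    genes, 0.9
  )
  expect_equal(library_summary(empty, genes)$genes_hit, 0)
  expect_error(assign_sites(sites, genes[0, ], 0.9), "empty")
})
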