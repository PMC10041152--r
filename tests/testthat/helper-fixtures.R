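# Small in-code fixtures shared across test files.

write_wig_text <- function(lines) {
  f <- tempfile(fileext = ".wig")
  writeLines(lines, f)
  f
}

toy_annotation <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    replicon_id = c("chr1", "chr1", "chr2"),
    start = c(101, 1001, 101),
    end = c(600, 1500, 700),
    strand = c("+", "-", "+"),
    product = NA_character_
  )
}

# random site tracks for property tests
random_track <- function(n, chroms = c("chr1", "chr2"), max_pos = 500) {
  pos <- sample.int(max_pos, n)
  tibble::tibble(
    replicon_id = sample(chroms, n, replace = TRUE),
    position = pos,
    count = rpois(n, 5)
  )
}

# independent step-up implementation of the Benjamini-Hochberg adjustment
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# enumerate every assignment of pooled values into groups of size n1/n2 and
# return the exact two-sided permutation p for the |log2fc of means| statistic
perm_brute_force <- function(x, y, psi = 0.01) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  obs <- abs(log2((mean(x) + psi) / (mean(y) + psi)))
  sel <- utils::combn(n, n1)
  stats <- apply(sel, 2, function(ii) {
    abs(log2((mean(pooled[ii]) + psi) / (mean(pooled[-ii]) + psi)))
  })
  mean(stats >= obs - 1e-12)
}
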