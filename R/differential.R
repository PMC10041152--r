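#' Pseudocounted log2 fold-change of fitness
#'
#' `log2((w_multi + psi) / (w_ref + psi))`. The pseudocount (default 0.01)
#' keeps the ratio finite when either mean fitness is zero (extinct
#' mutants).
#'
#' @param w_multi,w_ref Mean fitness in the multispecies and reference
#'   (single-bacterium) treatments; non-negative.
#' @param psi Pseudocount, `> 0`.
#' @return Numeric log2 fold-change(s).
#' @export
#' @examples
#' log2_fold_change(1.99, 0.99) # log2(2/1) = 1
log2_fold_change <- function(w_multi, w_ref, psi = 0.01) {
  if (psi <= 0) abort("psi must be > 0")
  if (any(w_multi < 0 | w_ref < 0, na.rm = TRUE)) {
    abort("fitness values must be non-negative")
  }
  log2((w_multi + psi) / (w_ref + psi))
}

#' Two-sample randomization test on the fitness log2 fold-change
#'
#' The observed statistic is `|log2_fold_change(mean(x), mean(y), psi)|`.
#' The null is generated by reassigning the pooled replicate values to two
#' groups of the original sizes. When the number of distinct assignments
#' is at most `n_perm` the full set is enumerated and the p-value is the
#' exact fraction of assignments whose statistic reaches the observed one;
#' otherwise `n_perm` random assignments are drawn and
#' `p = (1 + #{|stat*| >= |stat|}) / (n_perm + 1)`, which can never be 0.
#'
#' @param x,y Replicate-level fitness values for the two groups (each
#'   needs at least 2 defined values; otherwise `NA` is returned and the
#'   gene is untestable).
#' @param n_perm Number of random assignments when sampling (default 10000).
#' @param psi Pseudocount for the statistic.
#' @param exact `"auto"` (enumerate when feasible), `"always"`, `"never"`.
#' @param seed Optional integer seed for the sampling branch; the caller's
#'   RNG state is left untouched.
#' @return Two-sided p-value in `(0, 1]`, or `NA` if untestable.
#' @export
#' @examples
#' randomization_test(c(1, 1), c(2, 2)) # exact: 2/6
randomization_test <- function(x, y, n_perm = 10000, psi = 0.01,
                               exact = c("auto", "always", "never"),
                               seed = NULL) {
  exact <- match.arg(exact)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) return(NA_real_)
  pooled <- c(x, y)
  obs <- abs(log2_fold_change(mean(x), mean(y), psi))
  tol <- 1e-12

  n_assign <- choose(n1 + n2, n1)
  use_exact <- switch(exact,
    auto = n_assign <= n_perm,
    always = TRUE,
    never = FALSE
  )
  if (use_exact) {
    idx <- combn(n1 + n2, n1)
    stat <- apply(idx, 2, function(ii) {
      abs(log2_fold_change(mean(pooled[ii]), mean(pooled[-ii]), psi))
    })
    return(sum(stat >= obs - tol) / n_assign)
  }
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      ii <- sample.int(n1 + n2, n1)
      s <- abs(log2_fold_change(mean(pooled[ii]), mean(pooled[-ii]), psi))
      if (s >= obs - tol) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
  if (is.null(seed)) withr::with_preserve_seed(run())
  else withr::with_seed(seed, run())
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) with
#' input validation: every p must lie in `(0, 1]`.
#'
#' @param p Numeric vector of raw p-values (`NA`s allowed and preserved).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  pv <- p[!is.na(p)]
  if (any(pv <= 0 | pv > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Flag significance at an adjusted-p threshold
#'
#' @param results Tibble with a `p_adj` column.
#' @param alpha Significance level (strict inequality; default 0.05).
#' @return `results` with a logical `significant` column.
#' @export
call_significance <- function(results, alpha = 0.05) {
  mutate(results, significant = !is.na(.data$p_adj) & .data$p_adj < alpha)
}

#' Contrast multispecies-treatment fitness against the reference treatment
#'
#' For every gene and every multispecies treatment: the pseudocounted log2
#' fold-change of mean fitness relative to the single-bacterium reference,
#' a two-sample randomization test on the replicate fitness values, and
#' Benjamini-Hochberg adjustment performed within each contrast across
#' genes. Genes with fewer than two defined replicates in either group are
#' reported untestable (`p_raw = NA`).
#'
#' When the sampling branch of the randomization test is needed, each
#' gene's p-value uses a substream derived deterministically from `seed`
#' and the gene id, so results do not depend on gene order.
#'
#' @param fitness Tibble from [fitness_table()].
#' @param treatments Multispecies treatments to contrast; default every
#'   non-reference treatment present.
#' @param reference Reference treatment (default `"Rp"`).
#' @param psi Pseudocount (default 0.01).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @param n_perm Permutations for the randomization test (default 10000).
#' @param seed Experiment-level seed for the sampling branch.
#' @return Tibble `gene_id`, `contrast`, `treatment`, `W_multi`, `W_ref`,
#'   `log2fc`, `n_multi`, `n_ref`, `p_raw`, `p_adj`, `significant`.
#' @export
contrast_fitness <- function(fitness, treatments = NULL, reference = "Rp",
                             psi = 0.01, alpha = 0.05, n_perm = 10000,
                             seed = NULL) {
  present <- unique(fitness$treatment)
  if (!reference %in% present) {
    abort(paste0("reference treatment '", reference, "' not in fitness table"))
  }
  treatments <- treatments %||% setdiff(present, reference)
  ref_tbl <- fitness[fitness$treatment == reference, ]
  out <- list()
  for (tr in treatments) {
    mt <- fitness[fitness$treatment == tr, ]
    genes <- intersect(unique(mt$gene_id), unique(ref_tbl$gene_id))
    rows <- lapply(genes, function(g) {
      wx <- mt$W[mt$gene_id == g]
      wy <- ref_tbl$W[ref_tbl$gene_id == g]
      wm <- if (any(!is.na(wx))) mean(wx, na.rm = TRUE) else NA_real_
      wr <- if (any(!is.na(wy))) mean(wy, na.rm = TRUE) else NA_real_
      l2 <- if (is.na(wm) || is.na(wr)) NA_real_
            else log2_fold_change(wm, wr, psi)
      g_seed <- if (is.null(seed)) NULL else gene_substream_seed(seed, g, tr)
      p <- randomization_test(wx, wy, n_perm = n_perm, psi = psi,
                              seed = g_seed)
      tibble(
        gene_id = g,
        contrast = paste(tr, "vs", reference),
        treatment = tr,
        W_multi = wm, W_ref = wr, log2fc = l2,
        n_multi = sum(!is.na(wx)), n_ref = sum(!is.na(wy)),
        p_raw = p
      )
    })
    tab <- bind_rows(rows)
    tab$p_adj <- bh_adjust(tab$p_raw)
    out[[length(out) + 1]] <- call_significance(tab, alpha)
  }
  bind_rows(out)
}

# Deterministic 31-bit substream seed from an experiment seed and gene id,
# so per-gene sampling is reproducible regardless of gene order.
gene_substream_seed <- function(seed, gene_id, extra = "") {
  chars <- utf8ToInt(paste0(gene_id, "::", extra))
  h <- as.numeric(seed %% 2147483647)
  for (c in chars) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}
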