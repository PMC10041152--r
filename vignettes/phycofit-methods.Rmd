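---
title: "Mutant-pool fitness analysis for model phycospheres: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutant-pool fitness analysis for model phycospheres: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycofit)
```

## The experiment this package analyses

A dense pool of single-gene transposon mutants of a focal bacterium
(*Ruegeria pomeroyi* DSS-3 in the motivating system) is inoculated into
phytoplankton co-cultures, alone or together with other bacterial species,
and allowed to grow for several generations. Sequencing the
transposon-genome junctions before and after growth measures each mutant's
change in frequency; comparing a mutant's trajectory between community
compositions reveals which gene functions matter for life alongside other
bacteria — competition for shared substrates, crossfeeding of released
metabolites, chemically mediated antagonism, or adaptation to an altered
microenvironment.

The pipeline takes per-site insertion read counts (wig tracks, one per
sequenced sample), a gene annotation, sample metadata, and cell-abundance
measurements, and produces per-gene relative fitness values, treatment
contrasts with significance calls, and mode-classified reports.

## From reads to counts

Raw junction reads can be trimmed with `trim_junction_read()`: a read is
informative when the transposon's terminal motif (default
`AGATGTGTATAAGAGACAG`) starts within the first 60 bp; the 22 bases
following the motif are the genomic fragment used for mapping. Matching is
exact, and the first occurrence wins (the junction is the boundary nearest
the read start). Mapping itself is outside the package; the pipeline
consumes the resulting per-site count tracks.

`combine_wigs()` unions sites across samples, zero-fills gaps, and drops
sites with no reads in any sample — a position with no insertional mutant
carries no information about the pool.

## Library curation

Insertions very close to a gene's ends often leave a functional protein,
so only insertions within the central fraction (default 90%) of a coding
region count toward that gene. The window trims
`ceil(L * (1 - fraction) / 2)` positions from each end of a gene of length
`L`, which guarantees that at most `fraction * L` positions qualify; both
bounds are inclusive. The ceiling is a deliberate numerical choice: a
rounding rule must be fixed somewhere, and ceiling is the conservative
direction (never admitting more than the nominal fraction).

Strand is ignored during assignment — a transposon disrupts a coding
region on either strand. A site inside two overlapping central windows is
assigned to both genes (each gene's fitness is computed independently) but
counts once in the library totals; sites on unannotated replicons stay in
the pool totals without a gene assignment.

## Normalization and filtering

Counts are scaled per sample to the grand mean of per-sample totals
(`grand_mean_normalize()`), computed over *all* samples in the run
including the inoculum aliquots. Normalized counts stay fractional:
frequencies are ratios and re-rounding would only add error. Site counts
are then summed within genes (`aggregate_by_gene()`).

Genes whose reads are too sparse for a stable frequency estimate are
removed: a gene is dropped when the average of its inoculum-sample mean
and its grown-sample mean falls below 10 reads (strict inequality). The
two-timepoint mean is symmetric and robust to unequal replicate counts.
The filter is applied per treatment, so a gene may be testable in one
contrast and not another; removals are logged.

## Relative fitness

For mutant frequencies $N_{t1}$ (start) and $N_{t2}$ (end) and a pool
expansion factor $d$,

$$W \;=\; \frac{\ln\!\left(N_{t2}\, d / N_{t1} + 1\right)}
             {\ln\!\left((1-N_{t2})\, d / (1-N_{t1}) + 1\right)}.$$

$W = 1$ is pool-average growth, $W = 0$ is extinction, and a mutant whose
per-cell expansion is $d^{1/2}$ (half the pool's exponential rate) has
$W \to 0.5$ as $d$ grows. Both `+1` terms sit inside the logarithms; that
reading is forced by the anchors ($N_{t1} = N_{t2} \Rightarrow W = 1$ and
$N_{t2} = 0 \Rightarrow W = 0$) and is verified in the test suite.

The expansion factor is estimated by growth accounting
(`expansion_table()`): flow-cytometry total cell counts apportioned to the
focal species by CFU proportions at the two endpoints, with
`generations = log2(d)`. Each replicate's own `d` is used by default; a
treatment-mean `d` is a switch.

Two conventions are deliberate and documented because the field has no
single standard:

* **Start frequencies** come from the sequenced inoculum aliquots,
  averaged per gene before computing W — aliquots are sequencing
  replicates of one shared starting pool, not paired to flasks. Pairing
  is available as a switch (`pair_inoculum`).
* **Denominators**: frequencies are computed over the curated, filtered
  gene totals, so the frequency and count tables describe the same gene
  universe. (Using raw site totals instead changes every frequency by a
  common factor, which W is nearly insensitive to.)
* **Missing values propagate**: $N_{t1} = 0$ with $N_{t2} > 0$, or
  $N_{t2} = 1$, yield `NA` rather than a clamped value. The `+1` terms
  already regularize the common zero cases, and silent clamping would
  bias contrasts.

## Contrasts and significance

The treatment effect on gene $g$ is the pseudocounted log2 fold-change
$\log_2\!\big((W_{multi} + \Psi)/(W_{ref} + \Psi)\big)$ with
$\Psi = 0.01$, which keeps the ratio finite for extinct mutants.
Significance comes from a two-sample randomization test on the
replicate-level W values: the pooled values are reassigned to two groups
of the original sizes and the absolute log2 fold-change of group means is
recomputed. With four replicates per group there are only
$\binom{8}{4} = 70$ distinct assignments, so the test enumerates them
exactly instead of sampling; sampling (default 10,000 draws, with the
$+1/(n+1)$ correction so p is never zero) is used when the assignment
space is larger. Per-gene sampling substreams are derived
deterministically from the experiment seed, so results do not depend on
gene order. P-values are Benjamini–Hochberg adjusted within each contrast
and called significant at adjusted $p < 0.05$ (strict).

### Granularity of the 4-vs-4 randomization test

This design has a hard resolution floor that users should understand.
Because the achieving set of assignments is closed under swapping the two
groups, exact 4-vs-4 p-values are even multiples of $1/70$: the smallest
attainable p is $2/70 \approx 0.029$. Two consequences:

* Under a true null, the fraction of genes with raw $p < 0.05$ is exactly
  $2/70 \approx 2.9\%$ — slightly conservative relative to the nominal
  5%.
* Benjamini–Hochberg at 0.05 can only reject when at least
  $p_{min}/\alpha \approx 57\%$ of the tested genes sit at the minimal p.
  With sparse effects, *no* gene can reach adjusted $p < 0.05$ regardless
  of effect size; with dense effects (as in pooled competitions where a
  large share of genes respond, or in the recovery benchmark below) the
  adjustment passes essentially all minimal-p genes.

Finer resolution requires permuting a finer unit than replicate means
(for example per-site fitness values) or more replicates; both are
outside the present design, which permutes the quantity the contrast is
defined on.

## The synthetic experiment generator

`simulate_experiment()` produces complete experiments with known ground
truth in exactly the formats the io stage reads. Defaults mirror the
experimental design the package targets: ~15 insertion sites per gene (Poisson),
900-bp genes with a 10% intergenic site fraction, four treatments
(`Rp`, `Rp+V`, `Rp+M`, `Rp+V+M`) with four replicate flasks each plus
four inoculum aliquots, pool expansions of $2^{6.4}$ (single-species
reference) down to $2^{4.4}$ (three-species community) — the two
intermediate treatments interpolated at $2^{5.4}$, close to the reported
average of ~5.5 generations — and multinomial sequencing at $2\times10^6$
reads per sample (Dirichlet-multinomial overdispersion is a switch,
default off).

Growth is deterministic-exponential: a mutant with growth-rate multiplier
$m$ multiplies by $d^m$ while the pool multiplies by about $d$; noise
enters only through lognormal jitter on initial abundances (sdlog 1, a
realistic site-to-site spread after library bottlenecks) and read
sampling. Effects are parameterized as rate multipliers rather than
target W because W depends on depth and $d$; the implied true W is
computed in closed form ($\ln(d^m + 1) / \ln(D_{-g} + 1)$, with $D_{-g}$
the rest-of-pool expansion) into the truth table, along with the true
log2 fold-change versus the reference treatment.

**Relative fitness is compositional.** When some mutants crash, every
other mutant's frequency share — and therefore its true W *relative to
the pool* — genuinely rises. The truth table records these induced
shifts, and recovery tests judge discoveries against the ground-truth
fold-change (value and sign), not against the naive "had no multiplier"
label. This mirrors real pooled competitions, where "neutral" is always
relative to the pool's composition.

What the generator does **not** emulate: demographic (birth–death)
stochasticity, replicate-to-replicate biological variation beyond
sequencing noise, PCR/jackpot artifacts, chromosomal position effects,
polar effects of insertions on operons, and any diatom physiology.
Passing recovery tests therefore demonstrates correctness of the
estimator chain under the stated generative model, not robustness to
every artifact of real TnSeq data.

## Problem sizes and numerical choices

The test suite runs the full chain on 500-gene experiments at
$2\times10^6$ reads per sample for calibration and recovery (the
recovery benchmark spreads multipliers $\{0.25, 0.5, 1, 1.5\}$ evenly
across genes in the multispecies treatments), plus many smaller
property-based cases; the whole suite completes in well under a minute on
one core. Statistic comparisons in the permutation test use a $10^{-12}$
absolute tolerance so floating-point ties count as ties. Exact
enumeration supersedes sampling whenever the assignment space is not
larger than the requested permutation count.

## Mode classification

Mode assignment is annotation-driven, not inferred: the package ships a
curated mapping for the *R. pomeroyi* phycosphere mutant set
(`read_mode_annotation()`) covering the competition, crossfeeding,
chemically-mediated and altered-environment categories with their
published per-contrast fold-changes, and accepts user mappings with the
same columns. Significant genes absent from the mapping default to
`hypothetical`. Reports round to two significant figures for display;
machine-readable outputs keep full precision.

## Known limitations

* The randomization test's granularity floor (above) makes
  adjusted-p calls conservative for sparse effects at n = 4 + 4.
* The <10-read filter is applied per treatment; a gene's testability can
  differ between contrasts.
* Frequencies over curated, filtered genes mean the denominators differ
  slightly between treatments when the filtered sets differ; W is a
  ratio of frequency ratios and is nearly invariant to this.
* CFU-based species proportions assume equal plating efficiency across
  species; only proportions, not absolute CFU, enter the expansion
  factor.
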