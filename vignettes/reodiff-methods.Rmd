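---
title: "Individualized lncRNA differential expression from relative expression orderings: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{reodiff methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reodiff)
```

## The problem and the model

Population-level differential expression averages over patients, but many
lncRNAs are dysregulated in only a subset of tumors.  `reodiff` calls
differential expression **per sample**, using only the sample's internal
gene ranking, which makes the call invariant to scaling, library size and
most batch effects.

The reference criterion is a set of *stable pairs*: ordered gene pairs
$(a, b)$ such that $\mathrm{expr}_a > \mathrm{expr}_b$ (strictly) in at
least a fraction $f$ of the normal cohort.  For a gene $g$ in one tumor
sample, let

* $a$ = number of stable pairs in which $g$ is the high gene,
* $b$ = number in which it is the low gene,
* $c$, $d$ = how many of those same partners sit below / above $g$
  *in this sample* (ties always scored as a reversal of the reference
  direction).

Under no dysregulation, the sample proportion $c/(c+d)$ should match the
reference proportion $a/(a+b)$.  The call statistic is Fisher's exact
test (two-sided, minimum-likelihood rule) on
$\left[\begin{smallmatrix} a & b \\ c & d \end{smallmatrix}\right]$,
Benjamini–Hochberg adjusted **across genes within each sample**; a gene
with $q \le \alpha$ is called up if $c/(c+d) > a/(a+b)$, down if smaller.
An optional refinement pass re-tests every gene after excluding partners
themselves called non-zero, which de-contaminates the reference
proportions when many genes move at once; iteration stops at a fixed
point or `max_iter`.

The construction of the test statistic is a design choice of this
package: the rank-comparison literature this method descends from states
the contingency framing but leaves details (tie handling, FDR scope,
iteration) unspecified, so each is declared below and exposed as a
parameter.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `threshold_f` | 0.99 | fraction of normals that must agree for a stable pair; rank-comparison convention |
| `alpha` | 0.05 | within-sample BH FDR level for calls |
| `min_pairs` | 5 | minimum stable partners for a gene to be testable; below it the call is 0 with missing p |
| `max_iter` | 2 | total passes; 2 = one partner-exclusion refinement pass |

Choices made where the design was genuinely open:

* **FDR scope.** BH is applied within each sample across genes (a
  per-sample discovery set), not across the cohort: each patient's
  profile should be interpretable on its own.  The FDR procedure itself
  is BH; the original method's procedure is unstated.
* **Tie handling.** Ties in normals count against both directions of
  stability; ties in a tumor sample count as a reversal of the reference
  direction.  Both rules are conservative and deterministic.
* **Two-sided Fisher rule.** Minimum-likelihood summation, matching
  mainstream statistical software; mid-p and doubling variants exist and
  would give smaller/larger p.
* **Refinement.** Whether the original pipeline iterates is unstated;
  both modes exist here (`max_iter = 1` disables), and the single
  refinement pass is the default because one pass removes essentially
  all of the contamination in simulation while keeping cost linear.

## Downstream statistics

* **Cross-validation** (`kfold_paired_validation`): pairs are split into
  $k$ seeded folds; stable pairs are mined from training normals; calls
  on held-out tumors are scored against the sign of the paired
  tumor−normal delta, zero deltas counting as discordant.  The
  validated object is the per-test-sample call (not a training-set
  consensus direction); the source description admits both readings and
  this one is declared.
* **Fold-change contrast** (`fc_compare`): per-gene log2 FC is the
  median over pairs of $\log_2((t+1)/(n+1))$ (pseudocount 1, median not
  mean); called genes with majority-sign-consistent FC are compared to
  never-called genes within up/down strata by Wilcoxon rank-sum.
* **Omics consistency** (`consistency_ratio`): an up call is supported
  by amplification or hypomethylation, a down call by deletion or
  hypermethylation.  *Any* supporting flag makes the call consistent
  even when a contradicting flag co-occurs; called samples with no
  directional flag at all are excluded from the denominator.  Both
  conventions are declared (the source is silent on conflicts and
  coverage).
* **Subtype over-representation** (`over_represented`): one-sided Fisher
  of DE-vs-not against in-subtype-vs-rest, BH within subtype, plus a
  within-subtype DE frequency gate (> 5%) promoted from a display rule
  to a selection rule.  Specific = over-represented in exactly one
  subtype.
* **Co-occurrence** (`cooccurrence_network`): two-sided Fisher on
  direction-collapsed DE × alteration within a subtype's samples, kept
  at raw p < 0.05 with odds ratio > 1; no grid-wide correction, matching
  how such networks are usually reported.
* **Prognostic clustering** (`prognostic_filter`,
  `cluster_two_classes`): per gene, a two-group log-rank test of called
  vs unaltered samples (raw p < 0.05, at least 3 events per stratum);
  the retained genes' ternary call vectors are clustered with average
  linkage on Hamming distance and cut at $k = 2$, the larger class
  labelled 1.  The original selector and clustering parameters are
  unavailable; log-rank selection and Hamming/average linkage are this
  package's declared choices (a univariate Cox screen would be the
  natural alternative and gives the same ranking for binary strata).
* **Drug response**: clinical response uses direction-collapsed DE
  (two-sided Fisher among treated samples, raw p < 0.05); cell-line
  ActArea uses direction-specific grouping (default downregulated vs
  unaltered, Welch's t), because the two analyses are phrased that way
  in the source literature.  A significantly *lower* mean ActArea in the
  DE group flags resistance.

## The synthetic world

`generate_dataset()` emulates the statistical structure the pipeline
assumes; its defaults are the stated world and are not tuned to test
outcomes.

* **Expression** is log-normal: per-gene baseline log2 means with spread
  s.d. 2, within-gene noise s.d. 0.1 (a clean-normals world in which
  orderings are stable by construction), values $2^{\mu_g + \epsilon}$.
  Log-normal rather than count-based because the method consumes
  FPKM-like continuous values and only their orderings.
* **Universe sizes**: 300 genes, 50 reference normals, 200 tumors, every
  tumor paired.  Each tumor is an independent draw from the normal
  process (its matched normal is a separate draw) with planted shifts
  multiplied in; the alternative shared-draw reading would make every
  unplanted paired delta exactly zero and void the concordance and
  fold-change contrasts.
* **Planting**: each eligible gene carries one direction (down with
  probability $12.2/(12.2+6.8) = 0.642$) and is dysregulated in a
  binomial 9.8% of tumors, so the cohort mean down:up sample-fraction
  split lands on 12.2%:6.8% and the overall mean on 9.8%.  (The
  alternative — direction-specific per-gene frequencies 12.2%/6.8% with
  a 55:45 gene split — reproduces gene counts instead of
  sample-fraction targets; the sample fractions are what the package's
  checks measure.)  Planted $|\log_2 \mathrm{FC}|$ defaults to 4.
* **Structure**: 4 equiprobable subtypes with 3 subtype-specific genes
  each (DE 40% within, 2% outside); a latent 2-class split (class 2
  probability 0.25, mirroring a 67/23-style split) drives 5 prognostic
  genes (DE 60% vs 5%) and exponential survival (hazard ratio 3,
  5-year median baseline, uniform administrative censoring); alteration
  flags support each planted call with probability 0.9 over a 1%
  background; mutation burden and HRD score differ by class; drug
  response couples to 2 chosen genes with odds ratio 10, ActArea shifts
  by −1.5 s.d. under DE.
* **Determinism**: one global seed; every stage draws from a sub-stream
  keyed by its name, so outputs are byte-identical across runs and
  stable under stage re-ordering.

What the generator does **not** emulate: count noise and
mean–variance coupling, batch structure, correlated co-expression
modules, linked multi-omics beyond the stated couplings, or realistic
censoring patterns.  A green recovery test therefore establishes that
the statistics recover their own planted structure — not that the
pipeline reproduces any cohort-specific published figure, which would
require the original tumor data.

Two intrinsic limits of the ordering statistic are visible in this
world and worth knowing about: a gene near the top of the expression
distribution has almost no stable partners above it, so an *up* shift is
undetectable there (and symmetrically for down shifts at the bottom);
and when many genes shift at once, unshifted genes near a shifted gene's
band can be dragged into false calls, which is exactly what the
refinement pass corrects.  Recovery targets are met at the default
universe size; much smaller universes (&lt; ~100 genes) leave
low-abundance genes with too few below-partners for reliable down calls.

## Numerical choices

* Exact hypergeometric machinery throughout (`dhyper`/`phyper`); the
  two-sided rule includes tables whose point probability is within a
  $1+10^{-7}$ relative factor of the observed one, guarding against
  floating-point ties.
* The sample odds ratio $ad/bc$ is reported (infinite when $bc = 0$,
  `NaN` for doubly degenerate tables), not the conditional MLE.
* Wilcoxon is exact (via the null U distribution) for combined $n \le
  20$ without ties, otherwise normal with tie-corrected variance and
  continuity correction; the branch taken is reported.
* BH passes `NA` p-values through without counting them as tests.
* Clustering tie-breaks: samples are sorted by ID before distance
  computation; class 1 is the larger class, the class of the
  lexicographically first sample on exact ties.
* Missing values in all TSV formats are the literal `NA` (empty string
  accepted on read).

## Known limitations

* The all-pairs scan is $O(G^2 N)$ time and $O(G^2)$ memory; bound the
  universe with `gene_subset` beyond a few thousand genes.
* Per-gene p-values are not independent (partners are shared between
  genes), so within-sample BH controls FDR only in the usual
  positive-dependence sense.
* `prognostic_filter` uses marginal log-rank tests; no multivariable
  adjustment.
* Protein-coding mRNA profiles would work mechanically but are untested
  here; cross-platform pair transfer is out of scope.
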