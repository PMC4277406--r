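---
title: "Classifying tissue-specific expression from FPKM profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying tissue-specific expression from FPKM profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

## The model

`tissuespec` implements a rule-based classification of genes by where they
are expressed across a panel of tissues profiled by bulk RNA-seq. The
substrate is a gene × tissue matrix of replicate-averaged FPKM values
(arithmetic mean on the linear scale; FPKM is already length- and
depth-normalised, so means across replicates are comparable). Detection is
a hard threshold: mean FPKM at or above `detection_cutoff` (default 1)
counts as detected. The boundary value counts as detected because the
undetected class is defined by being *below* the limit of detection.

Seven mutually exclusive categories are assigned top-down, first match
wins:

1. **not detected** — below the cutoff in every tissue; in *focus mode*,
   below the cutoff in every focus tissue (the scheme's focus-set variant
   declares a gene undetected for the question at hand even if it is
   expressed elsewhere).
2. **highly tissue enriched** — top tissue at least 50× the second-highest
   tissue and detected.
3. **moderately tissue enriched** — the same with a 5× threshold.
4. **group enriched** — a group of 2–7 tissues whose mean FPKM is at least
   5× the maximum outside the group and at least the cutoff; in focus mode
   the group must include a focus tissue.
5. **enhanced** — some tissue at least 5× the mean of all other tissues
   together and detected; several tissues of one gene may qualify.
6. **expressed in all** — detected in every tissue.
7. **mixed** — everything else; this class is defined purely by exclusion,
   which is why the precedence order above is part of the definition (a
   5-fold enriched gene detected everywhere must not fall into
   *expressed in all*).

The ordered if-else chain makes the partition property structural: every
gene receives exactly one label.

### The group search

Candidate groups are the top-*k* prefixes of the profile sorted by
decreasing FPKM, for *k* from `group_size_min` to `group_size_max`; the
smallest qualifying *k* is reported as the most parsimonious group. In
global mode this prefix search is equivalent to exhaustive enumeration of
all subsets of allowed size: for fixed *k* the top-*k* prefix has the
largest possible mean and the smallest possible outside maximum, so it
qualifies whenever any *k*-subset does. The equivalence is asserted as a
property test against a brute-force subset oracle.

The focus constraint breaks that equivalence: a qualifying
focus-containing subset can exist while every qualifying prefix lacks a
focus tissue (the converse of parsimony). We define the focus-mode rule on
prefixes, matching the mechanical top-down reading of the scheme; the
alternative — exhaustive search restricted to focus-containing subsets —
would occasionally label additional genes at considerable combinatorial
cost and with a less interpretable "group".

### Numerical conventions

* Ties for the top tissue, and within sorted prefixes, break by
  lexicographic tissue name after a stable sort, so results are identical
  across platforms.
* When all non-candidate tissues are exactly zero the fold ratio is
  `Inf` and the criterion is vacuously exceeded; the detection-cutoff
  guard prevents noise-level genes (0.3 vs 0) from being called enriched.
  A group mean must likewise reach the cutoff.
* `outside_rank = 2` switches the group criterion's reference from the
  highest to the second-highest outside value, an alternative reading of
  "second highest of all other tissues"; the default (1, the outside
  maximum) is the only reading under which the single-tissue criterion is
  well defined, so both criteria use it consistently.
* Fold arithmetic always uses all tissues, also in focus mode; focus mode
  changes only the not-detected scope and the group membership constraint.
* All reported percentages round half-up (0.5 → 1), at one decimal below
  10% and as integers at or above 10%, mirroring the mixed precision in
  which such summaries are conventionally printed; shared fractions of
  differential sets round to whole percent.

## Comparative analyses

Correlation uses Spearman's rank coefficient with average ranks for ties —
appropriate for zero-inflated FPKM vectors — and returns an explicit `NA`
for constant columns rather than a warning-laden `NaN`. Clustering is
agglomerative with average linkage on the distance 1 − ρ computed on
log2(FPKM + 1) columns; the +1 pseudo-count keeps zeros finite on the log
scale. The scheme names neither distance nor linkage as canonical; a
rank-based distance matches the correlation statistic reported alongside,
and average linkage is the common choice for expression dendrograms. The
dendrogram is exported as Newick through `ape`.

Differential detection between tissues *a* and *b* is the asymmetric set
{mean FPKM ≥ cutoff in *a*, < cutoff in *b*}; cross-referencing splits
such a set by detection in at least one reference tissue.

## The enrichment network

The network summarises enriched genes as a bipartite graph: set nodes
(one per tissue with tissue-enriched genes, one per distinct enriched
group) connected to the tissues that define them. Group nodes survive
filtering when they hold at least two genes and span at most five tissues,
keeping the plot legible; node size is √(gene count), the usual area
scaling. Tissue nodes without any surviving set node are dropped — the
graph shows only populated structure. Exports (SIF and GraphML) sort
nodes by kind then name and edges by endpoint, so identical analyses
produce byte-identical files; both formats parse back losslessly (SIF
carries no attributes, by design of the format).

## The synthetic generator

Because the classifier's operating characteristics cannot be validated on
real data without a ground truth, the package ships a generator that
plants each category by construction and emits the truth table alongside
the matrix. It emulates a 27-tissue, ~20,050-gene profiling study:

* **Tissue panel and replicates.** 27 named human tissues; the four
  lymphohematopoietic tissues get their published replicate counts
  (bone marrow 4, lymph node 5, spleen 4, appendix 3) and the remaining
  tissues draw 1–5 replicates uniformly, giving on the order of 90
  samples.
* **Background expression** is log-normal on the log2 scale (mean 1.5,
  sd 1), a heavy-right-tailed stand-in for FPKM distributions; no
  distributional parameters are published for the real data, so these are
  explicit stand-ins, chosen once.
* **Default category counts** echo the published global proportions:
  3,500 tissue- or group-enriched genes (~17%), 9,222 expressed-in-all,
  and the remainder split between enhanced, mixed and not-detected, for a
  20,050-gene total.
* **Planted margins.** Enriched and group-enriched genes are drawn at
  2–4× their classification threshold (highly: 100–200× against 50×;
  moderately and group: 10–25× against 5×, capped below half the 50×
  threshold), so that multiplicative replicate noise at CV ≤ 0.2 almost
  never flips a call and noise-free classification recovers every label
  exactly. Enhanced genes use a three-level template (one elevated
  tissue, one runner-up blocking the tissue-enriched call, flat
  background) whose elevated value is drawn strictly between the enhanced
  bound and the group/moderate bounds. Mixed genes are generated by
  rejection sampling against the classifier itself, redrawing the
  detected-tissue subset each attempt, since the class is defined only by
  exclusion.
* **Replicate noise** multiplies each value by a log-normal factor with
  unit mean and configurable CV (default 0.1, which reproduces the
  qualitative pattern of replicate correlations ~0.95–0.98 against
  inter-tissue correlations below that).
* **Barcode leakage** emulates index hopping: within multiplexing pools
  of eight consecutive samples, each column becomes
  (1 − r)·own + r·mean(others), with r = 0.001 by default. This conserves
  each gene's total signal per pool exactly, as misassignment moves reads
  rather than creating them. Pool size is configurable; real multiplexing
  pool layouts are not modelled.

What passing tests on this generator do *not* show: robustness to
compositional effects, library-size or gene-length biases (FPKM is taken
as given), isoform-level complexity, or the correlated biological
variability of real replicates. The generator validates the
classification logic and its fold-margin arithmetic, not the upstream
quantification.

## Problem sizes used in validation

The test suite exercises the group-search oracle on 10,000 random
8-tissue profiles (where exhaustive enumeration over all 246 subsets of
size 2–7 is tractable), classifier/oracle equivalence on thousands of
fuzzed profiles, and label recovery on ten 5,000-gene, 27-tissue
simulations at CV 0.2 with 0.1% leakage plus one noise-free run — sizes
at which the full suite completes in about a minute while every category
is represented hundreds of times per run.

## Known limitations

* The classifier is gene-level; multi-isoform structure is out of scope.
* Focus-mode group search is prefix-based (see above); users wanting the
  exhaustive focus-constrained variant must enumerate externally.
* `expressed in all` uses the same ≥-cutoff detection convention as the
  rest of the scheme, so a gene exactly at the limit everywhere is
  expressed-in-all, not mixed.
* Percentage rounding matches printed-report conventions and is applied
  at reporting time only; all internal arithmetic is unrounded.
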