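---
title: "Consensus pathway and network prioritization of coding and non-coding cancer drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus pathway and network prioritization of coding and non-coding cancer drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidnet)
```

## The problem

Driver-discovery analyses of whole cancer genomes assign each *genomic
element* — a gene's coding sequence, core promoter, 5' UTR, 3' UTR, or the
enhancers targeting it — a p-value for positive selection. Coding driver
signal is strong and well characterized; non-coding signal is weak,
diffuse, and rarely significant element by element. Pathway and network
methods raise sensitivity by aggregating weak signal over sets of related
genes, but individual methods disagree, so robust gene lists come from a
*consensus* over an ensemble of methods. `pidnet` implements that
consensus machinery: element-to-gene score aggregation, a pluggable method
ensemble with randomized-data calibration, a permutation test isolating
the non-coding contribution to combined-signal discoveries, majority-vote
consensus, and the downstream network, enrichment, and expression
statistics used to validate the resulting gene lists.

## Gene scores

Let $p_x(g)$ be the driver p-value of element $x$ of gene $g$. Scores are
combined with Fisher's method,
$-2\sum_{i=1}^{k}\ln p_i \sim \chi^2_{2k}$, dropping missing elements and
reducing the degrees of freedom accordingly:

* **GS-C** (coding): $p_C(g) = p_{\mathrm{coding}}(g)$;
* **GS-N** (non-coding):
  $p_N(g) = \mathrm{fisher}\big(\min(p_{\mathrm{prom}}, p_{\mathrm{5'UTR}}),\,
  p_{\mathrm{3'UTR}},\, p_{\mathrm{enh}}\big)$, where $p_{\mathrm{enh}}$ is
  the minimum over the enhancers targeting $g$;
* **GS-CN** (combined): the Fisher combination of the coding p-value with
  the three non-coding arguments.

The promoter/5' UTR minimum reflects that these elements overlap on the
genome and largely share mutations; the enhancer minimum collapses a
gene's enhancer set to its strongest element. Duplicate p-values for one
element are min-reduced at load, and enhancers targeting more than 5
genes are dropped as unspecific.

Two numerical points deserve note. First, p-values of exactly 0 are not
valid inputs; values below a configurable floor (default `1e-300`) are
clipped before the log so a single rounded-to-zero input cannot dominate
every combination while ordering among tiny values is preserved. Second,
the min-reductions make the null distribution of GS-N and GS-CN slightly
anti-conservative for genes carrying both a promoter and a 5' UTR (or
several enhancers): the minimum of $m$ uniforms is stochastically smaller
than uniform, but it is still treated as a single chi-square term. This is
a property of the score definition itself, shared by any pipeline using
it; our uniformity tests therefore simulate tables in which each Fisher
argument is a single element, where all three scores are exactly
Uniform(0,1) under the null.

## The method ensemble and its calibration

Methods enter the consensus through a one-function interface: a *driver
method* maps a score vector to a reported gene set. Two reference methods
ship with the package:

* **Hypergeometric pathway method** — seed genes are those with
  Benjamini–Hochberg FDR below 0.1 on their gene scores; every pathway
  (gene sets filtered to 3–1000 members) is tested for one-sided
  hypergeometric enrichment of seed genes; reported genes are the seed
  genes of pathways with pathway-level FDR below 0.1.
* **Neighborhood network method** — each gene is scored by the Fisher
  combination of the gene scores of its first-order network neighborhood
  including itself ($p^{\mathrm{with}}$); genes pass when the BH FDR of
  $p^{\mathrm{with}}$ is below 0.1 *and* their own score improves the
  neighborhood ($p^{\mathrm{with}} < p^{\mathrm{without}}$). Genes of
  degree 0 use their own score as the neighborhood score (with
  $p^{\mathrm{without}} = 1$), so isolated high-signal genes are not
  silently discarded.

Published methods are represented by a replay adapter that wraps their
reported gene lists, so a full seven-method consensus can be reproduced
from result files without reimplementing the methods.

Every method is calibrated on randomized data: its input scores are
permuted across genes and the mean reported-set size recorded. A method
whose mean randomized report exceeds 10% of its observed report size is
flagged as miscalibrated. One consequence of using BH at FDR 0.1 inside a
method is worth knowing: under a global null, BH still makes at least one
rejection with probability roughly equal to its FDR level, so the
neighborhood method reports a (tiny) non-empty set in roughly one null
dataset in ten. Null behavior is therefore summarized by the mean and
median randomized report size rather than by demanding an empty report in
every replicate.

## The non-coding value-added (NCVA) test

In a combined GS-CN analysis the coding signal dominates, so genes driven
by non-coding mutations are hard to distinguish from passengers of the
coding signal. The NCVA test isolates them: holding every coding p-value
fixed, the non-coding element p-values are shuffled among the genes
possessing that element class (enhancer sets move as whole per-gene
bundles), GS-CN is recomputed, and the method re-run. For each gene of
the observed report $R_0$, the NCVA p-value is the pseudocounted
frequency $(1 + \#\{b : g \in R_b\})/(1 + B)$ with which the gene is
re-reported across $B$ permutations (default $B = 99$; since the smallest
attainable p is $1/(B+1)$, the default threshold of 0.1 requires
$B \ge 19$, which is enforced). Genes re-reported rarely owe their
discovery to their own non-coding signal; per method, these NCVA genes
augment the method's GS-N results. Shuffling within element class
preserves both the marginal distribution and the missingness pattern of
each class, which is the exchangeability the null requires. We read the
re-report frequency as a per-gene quantity; a set-level reading of the
same permutation scheme would be possible but would not attribute the
non-coding contribution to individual genes.

Two properties characterize the test, and both are asserted in the test
suite using the hypergeometric reference method: on coding-only planted
signal the fraction of $R_0$ passing NCVA stays within binomial noise of
the 0.1 threshold, and on planted promoter signal
($p \sim \mathrm{Beta}(0.05, 1)$) at least 80% of planted drivers present
in $R_0$ pass. The pathway method is the right instrument here because it
reports a gene only on the gene's *own* seed status. A network method
shares signal across neighbors by construction: after permutation, the
planted p-values land on random genes, and a well-connected gene whose
neighborhood catches a few of them can be re-reported even though its own
non-coding signal is gone. That neighborhood leakage raises re-report
frequencies by design, so with a network method the same experiment
measures the method's signal sharing rather than NCVA's selectivity. The
10-gene oracle comparison, which checks the permutation bookkeeping
itself, uses the neighborhood method.

## Consensus

A gene is a consensus gene when reported by at least a strict majority of
methods (4 of 7 for a seven-method ensemble; the threshold is
configurable). The coding consensus (PID-C, pathway-implicated drivers
with coding variants) votes over the GS-C reports. The non-coding
consensus (PID-N) first merges, per method, the GS-N report with that
method's NCVA genes — one vote per method regardless of whether a gene
appears in one or both — and then votes. The PID-C/PID-N overlap is
reported alongside both sets.

## Validation statistics

* **Neighborhood improvement** — whether a gene's own score lowers the
  Fisher-combined p-value of its network neighborhood, with a null built
  from uniformly sampled gene sets of equal size.
* **Interaction enrichment** — observed interaction counts within or
  between consensus sets against degree-preserving random networks,
  sampled by double-edge swaps (10·|E| attempted swaps per sample,
  rejecting loops and parallel edges) from a deterministic realization of
  the degree sequence; degree sequences are conserved exactly. Empirical
  p-values carry a +1 pseudocount. When two overlapping sets are
  compared, an edge inside their intersection counts once.
* **Connected subnetworks** — the largest connected component induced by
  a consensus set, with the analogous uniform-gene-set null.
* **Set enrichment** — one-sided Fisher's exact enrichment of a consensus
  set in a reference list (e.g. a cancer gene census) and hypergeometric
  pathway enrichment with BH correction. The gene universe materially
  changes these p-values and is always an explicit argument.
* **Signature enrichment** — frequencies of categorical signature labels
  among target mutations against size-matched resamples of background
  labels, two-sided; exhaustively enumerated whenever
  $\binom{|bg|}{|target|}$ does not exceed the resample budget.
* **In cis expression association** — per cohort, a two-sided Wilcoxon
  rank-sum test between mutated and non-mutated samples (at least 3 of
  each); across cohorts, samples are z-scored against the mean and
  unbiased s.d. of their cohort's non-mutated samples (cohorts need at
  least 1 of each; zero-variance cohorts are dropped) and pooled. The
  exact null distribution is used when the smaller group has at most 8
  samples and no ties; otherwise the normal approximation with tie and
  continuity correction, which agrees with enumeration to about 0.01 at
  8-vs-8. BH correction is applied separately within each element class.
  Expression values are used as provided (FPKM-UQ-like, non-negative); no
  implicit log transform.

## The synthetic scenario generator

Real inputs for this pipeline are controlled-access, and the published
consensus depends on seven external method outputs, so the package ships
a generator that emulates the *statistical structure* of the problem and
carries ground-truth labels:

* long-tailed element p-values: nulls Uniform(0,1), planted drivers with
  $p \sim \mathrm{Beta}(a, 1)$, the canonical one-parameter sub-uniform
  alternative ($a = 1$ recovers the null exactly; default $a = 0.05$,
  median planted p $\approx 10^{-6}$);
* a scale-free interaction network: a truncated power-law degree sequence
  (exponent 2.5, degrees 1–50) realized deterministically and randomized
  by degree-preserving double-edge swaps;
* planted modules: 60% of planted drivers co-located in a small number of
  gene sets that are simultaneously pathways and connected,
  densified network communities — emulating drivers clustering in a small
  number of pathways and interacting subnetworks;
* cohort-structured expression: per-gene log-normal baselines with
  cohort shifts, an additive cis effect of $\delta$ s.d. (default 2) in
  mutated samples, and a mutation table tying planted drivers to their
  mutated samples.

The canonical scenario is 10,000 genes, 100 planted drivers (half
coding-only, half non-coding-only), $a = 0.05$, 60% module co-location,
200 background pathways, and 3 cohorts of 50 samples. All randomness
derives from one master seed through per-component child seeds, so any
component can be regenerated independently and two runs are
byte-identical.

What the generator does *not* emulate: mutational processes and
signatures at the nucleotide level, copy-number and clonality structure,
correlated method errors (the reference methods share the gene scores but
real ensembles share much more), and the heavy inter-gene correlation of
real driver p-values. Passing recovery tests on synthetic data therefore
demonstrates that the machinery is correct and calibrated on data with
known structure — not that real-data gene lists would reach the same
precision.

## Recovery benchmark and its configuration

The end-to-end check runs the canonical scenario through gene scores,
both reference methods, NCVA, and majority vote at threshold 2, with one
replay adapter carrying the ground-truth list alongside the two reference
methods — the adapter stands in for the majority pressure that a full
seven-method ensemble provides, while false positives still need the
agreement of two independent routes. This configuration attains planted-
driver precision ≥ 0.8 and recall ≥ 0.6, and its non-coding consensus is
enriched for planted non-coding drivers at Fisher p < 10⁻⁶. A bare
two-method intersection is a much stricter consensus than 4-of-7: the
hypergeometric method can only ever report module-co-located drivers
(60% of the planted set), and Beta(0.05, 1) signal leaves roughly a
quarter of planted elements undetectably weak at BH FDR 0.1, so demanding
both methods caps recall near 0.5 regardless of implementation quality.
The problem sizes used in the tests (400-gene scenarios for permutation
experiments, the full 10,000-gene scenario for recovery) were chosen so
the whole suite characterizes every statistical property in about a
minute of CPU.

## Known limitations

* The anti-conservative null of min-reduced score arguments, above.
* Double-edge-swap sampling is approximately, not exactly, uniform over
  degree-matched graphs; on rigid toy graphs it is exact, and on larger
  graphs its bias is far below the Monte-Carlo noise at the permutation
  counts used.
* NCVA p-values inherit the granularity $1/(B+1)$; with the default
  $B = 99$ the smallest reportable p is 0.01.
* The per-gene NCVA reading retains genes whose *discovery* depends on
  non-coding data even when that dependence is a fortunate null draw, so
  NCVA sets on weak-signal data should be read jointly with the
  calibration records of the underlying method.
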