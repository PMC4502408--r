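---
title: "Reproducibility-based differential expression for technical-replicate designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility-based differential expression for technical-replicate designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repde)
```

## The problem

Drug-resistant and drug-sensitive cancer cell lines are clonal: technical
replicates of the same line carry measurement noise but no biological
variance. Experiments comparing such lines are typically tiny — two or three
replicates per phenotype — which leaves variance-based statistics (t-tests,
moderated t, SAM) with almost no degrees of freedom, while the conventional
fold-change cut-off offers no statistical control at all. `repde` implements
a different route: treat each pairing of one resistant (R) with one sensitive
(S) replicate as an independent experiment, rank genes within each pairing,
and keep exactly those genes whose *dysregulation direction* reproduces
across independent pairings far beyond chance.

## Scores and the reproducibility test

For a pair $j$ and gene $i$ with linear-scale (non-log) intensities $E^R_{ij}$
and $E^S_{ij}$, the two score rules are

$$PD_{ij} = E^R_{ij} - E^S_{ij}, \qquad PFC_{ij} = E^R_{ij} / E^S_{ij}.$$

A gene is *up-regulated* in the resistant line when $PD > 0$ (equivalently
$PFC > 1$), down-regulated otherwise; genes with $PD = 0$ or $PFC = 1$ carry
no direction and are excluded from the ranking. Lists are sorted by
decreasing magnitude, $|PD|$ for differences and $\max(PFC, 1/PFC)$ for
ratios, so an $x$-fold increase and an $x$-fold decrease rank equally (the
symmetric magnitude gives the same ordering as $|\log PFC|$). The two rules
look at different parts of the intensity range: differences are dominated by
strongly expressed genes, ratios reach down to weakly expressed ones — which
is also where multiplicative measurement noise is largest, the classic bias
of plain fold-change ranking.

Two direction-annotated lists sharing $k$ genes, $s$ of them with the same
direction, get the consistency score $s/k$ and the exact upper binomial tail

$$P(X \ge s) = \sum_{i=s}^{k} \binom{k}{i} p_e^i (1-p_e)^{k-i}, \qquad p_e = 0.5,$$

the probability of at least that much agreement when directions pair up at
random. A comparison is *significantly reproducible* when $p < 0.01$. The
tail is evaluated with `pbinom(..., lower.tail = FALSE)` and additionally on
the log scale, because comparisons of a few hundred genes routinely produce
p-values far below `1e-300`; `consistency()` therefore reports both
`p_value` and `log10_p`. Lists sharing no genes are flagged not-evaluable
rather than scored 0 — downstream code treats that as a failure to establish
consistency, never as evidence of inconsistency.

```{r}
fx <- consistency_examples()
consistency(fx$lists[[8]]$a, fx$lists[[8]]$b)  # 147 shared, 136 concordant
```

## Selecting reproducible sample pairs

With $r_1$ R replicates and $s_1$ S replicates there are $r_1 s_1$ pairings;
two pairings are *independent* when they share no sample. Selection works on
the top `top_n = 300` genes of each pairing's ranking: the independent duo
with the most significant consistency p-value seeds the selected set, and
remaining pairings are admitted one at a time when they are independent of
every selected pairing and significantly consistent ($p < 0.01$) with at
least one of them. A replicate with unreliable measurements drags all its
pairings to chance-level consistency (scores near 50%), so they are left out
with reason `inconsistent` — this quality gate is exactly how a failed
replicate is diagnosed without any external QC metric. Ties in the seed
choice (e.g. two duos both underflowing in p) are broken by higher score and
then lexicographic pair ids, which also makes the selection invariant to the
order in which samples appear in the input file.

## The block-wise consistency search

Given two ranked lists A and B from independent pairings, genes near the top
of both lists are the strongest DE candidates. The search partitions both
lists into blocks of `init_step` genes and walks down list A, comparing block
$A(i)$ against the cumulative prefix $B(1)\ldots B(i)$:

* while the consistency score of the shared genes is at least the threshold
  `ct`, the block is **accepted** and its direction-concordant shared genes
  are collected;
* on the first failing block $m$ the search **looks ahead** one block —
  if $A(m{+}1)$ vs $B(1)\ldots B(m{+}1)$ passes, the walk resumes there.
  The lookahead exists because a block can share only a handful of genes
  with the prefix, making its score unstable; failing block $m$ is *not*
  admitted on lookahead success;
* if the lookahead also fails, the step is **halved** and both lists are
  re-partitioned from the start of block $m$ with the finer step, so a
  consistent run at the top of the failed block can still be recovered at
  finer granularity. Halving repeats until blocks would drop below two genes
  (or `min_step`), or until a failing block shares no gene with the prefix.

Running the search in both orientations (A against B's top, B against A's
top) and merging gives the DE genes of that duo; with more than two selected
pairings, every duo is searched and the union is taken, deleting any gene
whose direction differs between two duo results. Because membership requires
identical direction in both lists of a duo, conflicts can only arise across
duos.

Several conventions in this search were genuinely open and are fixed here as
follows. The trailing `N mod k` genes form a short final block rather than
being dropped — it is only reached when every earlier block passed, where
inclusion is harmless. After halving, the cumulative B prefix is the already
partitioned region plus the new sub-blocks, i.e. it always restarts at
B(1). A block sharing zero genes with the prefix cannot be scored and is
treated as a failure; when the *failing* block itself has no overlap left,
the search exits rather than halving further, since no refinement can
recover genes that are absent from the prefix. Equal magnitudes in a ranking
are ordered by gene id, for platform-independent determinism. All of these
choices are locked in by an equivalence test against a literal, unoptimised
transcription of the block procedure on hundreds of randomised small
instances.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `ct` | 0.90 | minimum block consistency score; raising it to 0.95 shrinks the DE list, lowering it to 0.85 grows it |
| `init_step` | 300 genes | initial block size; too large lets weak genes ride along at the bottom of a passing block, too small makes scores unstable and terminates the search early |
| `top_n` | 300 genes | list prefix used when screening sample pairs |
| `p_e` | 0.5 | null probability of direction agreement |
| p threshold | 0.01 | significance level for "reproducible" |
| `floor` | 1.0 | intensity floor applied before ratio scoring |

The floor guards `PFC` against division by zero or near-zero intensities; on
typical microarray scales (median intensities in the hundreds) a floor of 1
only touches values that are noise anyway. It is user-overridable.

## Preprocessing

`repde` expects already-summarised intensity matrices. For platforms whose
standard pipeline ends in log2 + quantile normalisation, the helper
`quantile_normalize_log2()` (backed by `limma::normalizeQuantiles`,
average-rank tie convention) applies that step and returns *linear*-scale
values, since both scores are defined on non-log intensities. Probe-to-gene
collapsing averages probes on the log2 scale (`collapse_probes()`). Rows
with missing values are dropped with a message rather than imputed — the
algorithm has no missing-data contract. Platform-specific summarisation such
as RMA is expected to happen upstream.

## Pathway enrichment

`enrich()` tests each supplied gene set (GMT format) for over-representation
of the DE list with the exact hypergeometric upper tail
$P(\text{count} \ge X)$ given set size $M$, DE-list size $K$ and universe
size $N$ (all measured genes after preprocessing), and adjusts across all
sets that intersect the universe with the Benjamini–Hochberg step-up rule,
flagging sets with FDR < 5%. A DE list must contain a substantial fraction
of genuine signal for *any* set to survive adjustment: random gene lists of
the same size almost never enrich anything, which the test suite verifies on
a synthetic collection (150 sets of 20–200 genes over a 10,000-gene
universe, 1000 random draws).

## The synthetic-data generator

`simulate_expression()` emulates the structure the method assumes, and is
the basis of all end-to-end tests:

* clonal phenotypes: every replicate of a phenotype shares one true profile;
* intensity-dependent technical noise on the log2 scale with
  $\mathrm{sd} = a + b/\sqrt{\mu}$ (defaults $a = 0.05$, $b = 2$: about
  0.07 log2 units at intensity 10,000 and 0.47 at 25), reproducing the
  instability of fold changes at low intensities;
* planted DE in the two regimes the two score rules target: 100 genes at
  high baseline (log2 $\approx 11$) shifted by an additive 3000 intensity
  units (large $|PD|$, modest ratio), and 100 genes at low baseline
  (log2 $\approx 4.5$) scaled 6-fold (large ratio, small $|PD|$), directions
  assigned at random;
* 2000 genes and a 3 vs 3 replicate design by default, the shape of the
  cell-line datasets this method was designed around, with 2 vs 2 also
  exercised in the tests;
* optionally, a *corrupted* replicate whose profile is re-drawn
  independently of the genes' true levels — pairings containing it have
  chance-level consistency with good pairings and are excluded by the pair
  selection, emulating the failed-replicate case.

The effect sizes were calibrated once in pilot runs against the ground-truth
labels so that the planted signal is strong, cleanly separated from the
noise floor — the regime the method claims — and then frozen together with
the seed. What the generator deliberately does **not** emulate: batch
effects, probe-level artefacts, correlated noise between genes, biological
variance, or the mixed effect sizes of real resistant lines. Passing the
recovery tests therefore shows the algorithm does what it promises under its
own assumptions, not that it would reach the same recall on real arrays.

## Scale of the shipped checks

The packaged tests run the full pipeline on the 2000-gene default
simulation, the corrupted-replicate screen over 100 seeds, the
block-search/oracle equivalence over 500 randomised instances of up to 60
genes, and the enrichment null over 1000 random draws — sizes chosen so the
whole suite completes in a couple of minutes while every behavioural claim
above is exercised.

## Limitations

The method ranks and filters; it does not estimate a false discovery rate
for the gene list itself — reproducibility across technical pairings removes
irreproducible noise but cannot certify biological truth. It is intended for
clonal material measured with technical replicates; with biological
replicates (tissue samples), between-sample variance violates the premise
that paired experiments should agree, and variance-based methods on adequate
sample sizes are the right tool. Selecting pairs by consistency could in
principle bias towards agreeing noise, but with no biological variance the
prior probability that two good technical pairings agree is high, so the
gate mostly removes genuinely failed measurements.
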