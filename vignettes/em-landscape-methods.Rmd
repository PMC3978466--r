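---
title: "Methods: mapping the extracellular-milieu transcriptional landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the extracellular-milieu transcriptional landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emlandscape)
```

## The problem this package addresses

In congenic mouse models of Sjögren's syndrome — C57BL/6.NOD-*Aec1Aec2*
animals carrying the two susceptibility intervals *Aec1* (chromosome 3,
0–46 cM) and *Aec2* (chromosome 1, 29.7–106.1 cM) on a C57BL/6 background —
disease develops silently over weeks before overt dysfunction. The analytic
question is which coordinated transcriptional programs change in the
salivary gland **between consecutive ages** in the diseased strain, over and
above the developmental changes that the healthy background strain shows
anyway, and how strongly those programs revolve around the extracellular
milieu (EM): the cell periphery, the extracellular matrix, and cell–cell
junctions.

`emlandscape` implements that pipeline end to end on any two-strain,
multi-timepoint, replicated log-scale expression matrix:

1. **Ranking** genes between the two chronologically closest timepoints
   within one strain by the SAM relative-difference statistic.
2. **Preranked GSEA** of a gene-set collection on each ranked list, with
   permutation p-values, normalized enrichment scores (NES), FDR q-values,
   leading-edge (LE) extraction and the TAGS / LIST / SIGNAL descriptors.
3. **Strain contrast**: gene sets significant in both strains with the same
   direction over the same period (*parallel*) are treated as normal
   development and discarded; sets significant in the diseased strain only
   (*exclusive*) or with opposite directions (*reciprocal*) are retained.
4. **EM networks**: retained sets are qualified as EM-related (GO ancestry)
   or EM-associated (LE overlap with an EM-related set), connected by
   LE-overlap edges, and clustered with the Markov cluster algorithm (MCL).
5. **Metanode gene clouds**: each MCL cluster is collapsed and its LE genes
   are weighted by how many member sets carry them.
6. **Locus dependence**: per retained set, the percentage of LE genes inside
   the susceptibility intervals, compared across curated biological themes
   by one-way ANOVA with Tukey's post hoc test.

## The ranking statistic

For a gene with replicate vectors $x_1$ (earlier age) and $x_2$ (later age),

$$d = \frac{\bar x_2 - \bar x_1}{s + s_0}, \qquad
s = \sqrt{\left(\tfrac1{n_1}+\tfrac1{n_2}\right)
\frac{\sum (x_1-\bar x_1)^2 + \sum (x_2-\bar x_2)^2}{n_1+n_2-2}},$$

so positive $d$ means upregulation at the later age. The fudge factor $s_0$
prevents genes with tiny scatter from dominating the ranking; it acts as a
non-arbitrary fold-change criterion, which is why no explicit fold-change
cutoff appears anywhere in the pipeline. By default $s_0$ is chosen from the
percentiles $\{0, 5, \dots, 100\}$ of the per-gene scatter distribution by
minimizing the coefficient of variation of the spread of $d$ across
scatter-quantile windows (a `median` policy and a `fixed` value are offered
for reproducibility; the choice only perturbs ranks of low-scatter genes).
SAM is used **only to rank**: no SAM delta table or permutation FDR is
computed, because significance is assessed downstream at the gene-set level.

## The enrichment score and its descriptors

Walking down the ranked list of $N$ genes, a set with $N_H$ detected members
accumulates $|d_i|^p / N_R$ at each member ("hit", with $N_R$ the sum of
those weights; $p = 1$ by default) and loses $1/(N-N_H)$ at each non-member.
The enrichment score ES is the running sum's value at its maximum absolute
deviation; the **leading edge** is the members at or before the peak
(positive ES) or at or after it (negative ES). With $p = 0$ the statistic
reduces to the classical Kolmogorov–Smirnov form, and the test suite checks
that reduction explicitly. Ties between the positive and negative extremum
(exact rational ties occur routinely for single-member sets) are resolved to
the **first** index attaining the extremum, recognized at floating-point
resolution ($10^{-12}$); implementation and brute-force oracle share this
convention.

Per result we report, as percentages:

* **TAGS** $= 100\,|LE|/N_H$ — how much of the set drives the signal;
* **LIST** $= 100\,\text{peak}/N$ (positive ES; mirrored for negative) —
  where in the list the peak sits;
* **SIGNAL** $= \text{TAGS}\cdot(1-\text{LIST}/100)\cdot N/(N-N_H)$, capped
  at 100 — the combined strength descriptor.

### Null model, p-values and FDR

Because the input is a preranked list, phenotype permutation is impossible;
the null is **gene-set permutation**: random same-size member sets drawn
from the universe, with draws shared across sets of equal detected size and
fully determined by the run seed. The nominal p-value is two-sided on the
magnitude of ES,

$$p = \frac{\#\{|ES^*| \ge |ES|\} + 1}{n_{perm} + 1},$$

with the add-one correction avoiding impossible zero p-values; at the
default 1,000 permutations the smallest attainable p ($\approx 0.001$)
still clears the 0.005 significance gate. This two-sided form is calibrated:
on random sets against a random list the fraction with $p < 0.05$ sits at
0.05 within Monte-Carlo error (an acceptance test asserts this within three
binomial standard errors). NES and FDR follow the reference GSEA procedure
and remain sign-conditioned: $NES = ES / \operatorname{mean}|ES^*|$ over
same-signed permutations, and the FDR q-value is the tail ratio of the
pooled permutation NES distribution to the observed NES distribution,
computed separately per sign and clamped to $[0, 1]$.

Gene sets enter GSEA only if, **after intersection with the detected
universe**, they have strictly more than 10 and strictly fewer than 1,000
members — the statistics are only defined over detected genes, so the filter
is applied after the intersection.

## Significance criteria and the strain contrast

A result passes when FDR $< 0.05$ (strict), nominal $p < 0.005$ (strict) and
TAGS $\ge 50\%$ (non-strict). The same three-part gate is applied to both
strains; the criteria are symmetric because the parallel/reciprocal
definitions compare like with like. Sets passing **only** in the control
strain fit neither the exclusive nor the parallel definition; they form a
fourth, logged-but-dropped category. Classification is exhaustive over the
eight pass/fail-by-direction combinations, and a parallel set can never
reach any downstream network, cloud or locus table (asserted end to end in
the tests).

## EM qualification, connectivity and clustering

**EM-related**: a GO set with FDR $< 0.05$ whose term is, or descends from
(via `is_a`/`part_of`), GO_0071944 (cell periphery), GO_0031012
(extracellular matrix) or GO_0005911 (cell–cell junction). A root term
itself qualifies — the ECM term appears as a network node in its own right.

**Connectivity** between two sets is the percent overlap of their LE gene
sets. The denominator is configurable; the default is the **Jaccard** form
(shared / union), chosen as the symmetric, union-referenced reading of
"shared LE members" — the overlap-coefficient form (shared / smaller set) is
available via `method = "overlap"`. Edges require connectivity $\ge 8\%$
(inclusive). **EM-associated**: a set passing the full three-part criteria
with a qualifying edge to at least one EM-related set. All supra-threshold
edges among qualified nodes are kept, including those between two
EM-associated sets; EM-related sets without a qualifying edge remain as
isolated nodes.

**MCL** runs on the connectivity-weighted adjacency with self-loops set to
the maximum incident weight: column-normalize, then alternate expansion
(matrix squaring) and inflation (entrywise power 2.5, renormalize) until the
matrix changes by less than $10^{-8}$; entries below $10^{-14}$ are pruned
each sweep for numerical stability. Clusters are the connected components of
the limit matrix's non-zero structure, labeled by descending size with ties
going to the lexicographically smallest member. Inflation 2.5 with
max-weight self-loops follows common enrichment-map practice; both are
exposed as arguments. The partition is deterministic and invariant to node
relabeling and to uniform scaling of the edge weights (both are tested, the
latter following from column normalization).

Node attributes mirror the display conventions: triangles for EM-related,
circles for EM-associated; node size scaled against a 50-gene reference set;
label size against a TAGS of 75%; a border marks reciprocal alterations;
edge color carries the connectivity. Networks are exported as GraphML and
SIF with full attribute tables, so a Cytoscape edge-weighted spring layout
reproduces the intended rendering; `autoplot()` gives a seeded
force-directed preview.

## Metanodes and gene clouds

Each MCL cluster collapses into a metanode (size scaled against a 15-set
reference). Its gene cloud lists every gene in any member LE with a
frequency equal to the number of member sets carrying it — the display
weight. The cloud's color groups operationalize "clustering of the LE genes
by the connections of their sets", which has no canonical formalization: we
re-run MCL on the metanode's internal subgraph and assign each gene to the
sub-cluster in whose sets it occurs most often, ties to the smaller label.
This is an explicit, documented surrogate; any rule that respects the
internal block structure would color the planted fixtures identically.

## Locus dependence

Per retained set, the locus fraction is the percentage of its LE genes lying
in any susceptibility interval (closed in cM; overlapping intervals never
double-count). Genes without a map position count as outside — the
conservative reading. Theme membership is an input mapping, since themes are
curated, not algorithmic. Themes with at least two sets are compared by
one-way ANOVA (`stats::aov`) with Tukey's HSD post hoc test
(`stats::TukeyHSD`); stars follow the $0.05 / 0.01 / 0.0001$ convention. If
every fraction is identical the ANOVA F is defined as 0 with nothing
significant (the standard estimator is 0/0 there). Both per-set fractions
and per-theme LE-gene union counts are emitted, as the two views answer
different questions (average reliance per pathway vs total genetic load per
theme).

## The synthetic-data generator

`simulate_study()` emulates the study design the pipeline assumes: two
strains (diseased and control background), ages 4/8/12/16 weeks, five
replicates per cell. Per gene, a baseline $\sim N(8, 1)$ on the log2 scale
with replicate noise $N(0, 0.25)$ — the magnitudes typical of normalized
microarray data. Planted sets receive an additive log2 shift (default 1.5)
from the target age onward, in the diseased strain only (exclusive), in both
strains (parallel), or with opposite signs (reciprocal); sets sharing a
block also share 30% of their members, so networks have real edges, and a
block's shift is applied once (shared genes are never shifted twice, which
is why blocks must plant compatible shifts). Planted GO sets receive
synthetic terms descending from the three EM roots in a small generated DAG;
background GO sets descend from a neutral root. Each planted gene lands
inside a susceptibility locus with its set's `locus_frac` probability, so
themes can differ in locus dependence by design. Defaults are small
(2,000 genes, ~80 sets) so full-pipeline tests run in seconds.

What the generator does **not** emulate: probe-level artifacts,
correlated noise between genes outside planted sets, heavy-tailed intensity
distributions, batch structure, or sets overlapping in complicated
non-block patterns. Passing tests therefore demonstrate the machinery's
correctness and power under clean conditions, not performance on real
arrays; on real data the FDR behavior depends on inter-gene correlation
that gene-set permutation does not model (a known property of preranked
GSEA, inherited here).

## Problem sizes and numerical choices

The test and benchmark runs use 2,000–2,500 genes, ~60–90 gene sets and
200–1,000 permutations — sizes chosen so a full suite completes in a couple
of minutes while leaving every statistical property measurable. The recovery
benchmark (`benchmark_plants()`: 20 exclusive, 4 reciprocal, 4 parallel sets
of 40 genes, 1.5 log2 shift, noise 0.25, 5 replicates) is scored against
ground truth on retention and class agreement. Permutation draws, layouts
and simulations are all seeded; a pipeline run writes a manifest (seed,
parameters, md5 per output file, no timestamps) that is byte-identical
across same-seed runs.

## Known limitations

* Probe collapse keeps the single highest-mean probe; splice-level signal is
  lost by design. Multi-gene probes are assigned to each mapped gene.
* The nominal p floor at $1/(n_{perm}+1)$ means FDR estimates saturate for
  many strong sets at once; q = 0 rows should be read as "below resolution".
* MCL on dense, near-uniform networks can return one cluster; inflation is
  the only lever and is data-dependent.
* The 8% connectivity threshold and the Jaccard denominator are conventions,
  exposed as arguments; the qualitative network structure is stable around
  them but edge counts are not.
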