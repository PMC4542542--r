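---
title: "Relating lineage relatedness to environmental affinity: models and methods"
author: "lineageAffinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating lineage relatedness to environmental affinity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineageAffinity)
```

## The scientific question and the inference chain

Closely related diatom lineages — distinct *rbcL* sequence types a few
nucleotides apart — can be recovered both from the surface sediments of
many lakes and from dated horizons of a single sediment core. If the
distribution of such lineages is shaped by the environment, closely
related lineages should occupy similar environments (here: vegetation
types across the tundra–taiga treeline, or periods of similar *Larix*
pollen abundance in a core); if it is shaped by geography, relatedness
should instead follow the sampling transects. `lineageAffinity` formalises
this comparison as a chain of testable steps:

1. **Clones → lineages.** Cloned PCR products are dereplicated into
   sequence types; a type is accepted as an authentic lineage only if it
   was observed in at least `minClones = 2` clones from at least
   `minPcrs = 2` independent PCRs. The rationale is that a polymerase
   error arises in one molecule of one reaction and is overwhelmingly a
   singleton, while a true template reamplifies across reactions. Both
   thresholds are explicit arguments: the defaults are a standard
   clone-error exclusion rule, not a published constant.
2. **Lineages → distances.** Uncorrected pairwise nucleotide counts
   (`hammingMatrix()`; by default a site contributes only when both
   characters are unambiguous bases) summarise within-group divergence.
   Evolutionary relatedness is the patristic distance: the sum of branch
   lengths along the tree path between two tips. Trees are consumed as
   Newick with mandatory branch lengths; rooting does not affect path
   sums. Tree inference itself is out of scope — trees come from external
   (e.g. Bayesian) inference, with `njTree()` provided only so synthetic
   pipelines are self-contained.
3. **Occurrences → affinities.** With presence/absence data the relative
   frequency of a lineage in a lake is 0 or 1, so the mean relative
   frequency within a category, corrected for category size, reduces to
   the within-category occupancy proportion
   \(A(i,c) = n_{ic}/N_c\). This is how `categoryAffinity()` interprets
   "mean relative frequency corrected for the number of lakes": the
   proportion is invariant to duplicating every sample of a category,
   which is precisely the correction for unequal category sizes. The
   *Larix* pollen affinity is the occupancy-weighted mean
   \(LA(i)=\sum_s x_{is} p_s / \sum_s x_{is}\), a convex combination of
   the occupied horizons' *Larix* percentages.
4. **Affinities × distances → inference.** Distance-based redundancy
   analysis (dbRDA) asks how much of the lineages' patristic structure is
   explained by their affinity columns, with significance from row
   permutations and the explanatory set chosen by forward selection at
   p < 0.1.

Abundances are never used beyond presence/absence: clone frequencies are
at best semi-quantitative after PCR and cloning, so every matrix entering
the analyses is binarised (and the pipelines log that step).

## The ordination engine

The constrained-ordination machinery is implemented in the package rather
than delegated, so that every numerical choice is explicit; the test suite
cross-checks it against vegan (`rda`, `capscale`, `monoMDS`) and against
closed forms and brute-force oracles.

**RDA.** The response matrix is column-centred; with \(H\) the orthogonal
projection onto the span of the centred explanatory columns,
\(R^2 = \lVert HY \rVert_F^2 / \lVert Y \rVert_F^2\),
\(\mathrm{adj}R^2 = 1-(1-R^2)\frac{n-1}{n-m-1}\) (Ezekiel) with \(m\) the
rank of the constraints, and the statistic
\(F = \frac{R^2/m}{(1-R^2)/(n-m-1)}\) is referred to its permutation
distribution under row permutation of the explanatory matrix. P-values
use the add-one estimator \((1+\#\{R^2_{perm}\ge R^2\})/(1+n_{perm})\);
`nPerm` defaults to 999. Rank-deficient designs are fit at their actual
rank with a warning; zero-variance designs are an error.

**PCoA and dbRDA.** PCoA is Gower double-centring
\(G=-\frac12 J D^{(2)} J\) followed by an eigendecomposition; coordinates
are eigenvectors scaled by the square roots of the positive eigenvalues.
Bray–Curtis and patristic matrices need not be Euclidean, so negative
eigenvalues occur; the default policy `drop` retains the positive axes
only and reports total inertia as their sum, with Lingoes (constant added
to squared distances) and Cailliez (constant added to distances) available
when a fully Euclidean representation is wanted. dbRDA is RDA on all
retained PCoA axes; on Euclidean distances of a raw matrix it reproduces
the RDA of that matrix to numerical precision, which is the engine's core
correctness oracle (asserted at 1e-9 over random datasets).

**Forward selection.** Greedy: at each step the candidate adding the most
R² (ties broken by label) is tested conditionally — its residuals off the
current model are permuted — and admitted if p < `alpha` (default 0.1,
the printed rule). Selection stops when no candidate qualifies; an empty
selection still reports the best candidate's diagnostics. The more
conservative double stopping rule (global test plus adjusted-R² ceiling)
is deliberately not applied, because the implemented rule is exactly the
single threshold stated for the analyses this package reproduces.

**NMDS.** Kruskal stress-1,
\(\sqrt{\sum (d_{ij}-\hat d_{ij})^2 / \sum d_{ij}^2}\), where \(d\) are
configuration distances and \(\hat d\) their isotonic (PAVA) regression on
the rank order of the input dissimilarities (primary tie treatment), is
minimised by alternating the monotone-regression step with a Guttman
transform. One start is the PCoA configuration, the remaining
`nStarts = 20` are random; convergence is a stress change below
`tol = 1e-6` within `maxIter = 300` iterations; the best start is
returned, centred and rotated to principal axes. Stress is
scale-invariant, and the optimizer is validated against a dense
grid-search oracle on a four-point instance.

**Permutation validity.** Under exchangeable nulls the rejection rate of
the RDA/dbRDA permutation test at \(\alpha = 0.05\) stays within the
binomial 99% confidence band of 0.05 (asserted over 1000 simulated
datasets at 199 permutations in the acceptance tests).

## The synthetic-data generator

The generator exists so that every downstream stage can be exercised,
end to end and with known truth, without any external data. Its defaults
emulate the targeted study design:

* 14 lineages of a 67-bp fragment (configurable up to the ~23 of the
  longer fragment), on a Yule tree (`ape::rphylo`, birth 1, death 0);
* Jukes–Cantor sequence evolution with per-branch per-site substitution
  probability \(p = \frac34(1-e^{-4\mu t/3})\); the default
  `mutationRate = 0.015` substitutions/site per unit branch length gives
  a few percent mean pairwise divergence on a unit-rate Yule tree, the
  level observed between closely related *rbcL* sequence types;
* 21 lakes in 3 transect blocks, each block spanning the 4 ordered
  vegetation types (tundra → taiga), so that the environmental and
  geographic factors are crossed as in the real sampling design;
* a 20-horizon core (132 cm, ~7000 years at a constant accumulation
  rate) whose *Larix* percentage declines linearly from 6% (oldest) to 1%
  (youngest) plus Gaussian noise (`larixNoiseSd = 0.5`), clipped at 0;
* clone libraries of 20 clones per template tagged round-robin across 2
  independent PCRs, with per-site polymerase error probability 0.002.

**Niche model.** Lake occupancy follows a Gaussian niche over the ordered
category index: \(P(\text{present}) = b\,
e^{-(o_i - c_s)^2 / 2w^2}\) with baseline \(b\) (`occupancyBaseline`,
default 0.9) and width \(w\) (`nicheWidth`, default 0.5 category units) —
the strong-signal preset. Under the environment scenario the category is
the vegetation type; under geography, the transect; under null, occupancy
is a constant \(b\). The core uses the same rule with the *Larix*
percentage as the axis, optima and width rescaled onto the observed
*Larix* range. Lineages drawn absent from every lake are redrawn (at most
100 times — a lineage never observed cannot enter any analysis); all-zero
core horizons are allowed and kept.

**Niche optima.** The niche optimum of each lineage lives on the bounded
gradient \([1, K]\) via a logistic squash of a tip-level trait. The trait
is a weighted blend \( \sqrt{w}\, s_i + \sqrt{1-w}\, b_i \) of (a) the
lineage's standardized score on the leading principal-coordinate axis of
the patristic distance matrix — a deterministic "relatedness gradient" —
and (b) one standardized Brownian-motion realization on the tree.
`nicheSignal` is the weight \(w\) (default 0.85). The pure Brownian model
(\(w = 0\)) is included, but a single scalar Brownian draw only sometimes
realizes tree-structured trait similarity: the realized trait difference
across the deepest split is one Gaussian draw, so in a large fraction of
realizations even the true optima explain little of the patristic
structure, and no analysis could recover a signal that the realization
did not contain. The deterministic component is what makes
"closely related ⇒ similar niche" reliably true in the generated worlds,
which is the property the environment scenario is meant to emulate; the
default weight was fixed by Monte-Carlo against the generator's design
targets (vegetation-affinity dbRDA significant and transect-affinity
dbRDA non-significant in well over 80% of environment-scenario
replicates, mirrored under geography) and is not revisited by any test.

**What the generator does not emulate.** No indels, no rate
heterogeneity across sites or branches, no chimeras, no sequencing
quality, no spatial autocorrelation within transects, no taphonomic DNA
degradation down-core, and no covariation of the lake physico-chemistry
with the vegetation gradient (the real system has strongly co-varying
limnic variables). Passing tests therefore demonstrate the correctness
and statistical calibration of the machinery on data satisfying the
stated model — not that real sedimentary DNA meets these assumptions.

## Numerical and interface conventions

* Coordinates are 0-based half-open everywhere a window is specified
  (`trimToSubfragment(x, start, end)`), so the 67-bp window inside a
  191-bp fragment is a configuration value.
* Hamming distances default to `skip_ambiguous` (a site counts only when
  both characters are A/C/G/T); percentages always use the full fragment
  length as denominator. Distance summaries report to one decimal.
* Dereplicated type ids are assigned by descending clone count with ties
  broken by sequence lexicographic order — purely for reproducibility.
* Affinity-space distances are Euclidean by default (the metric dbRDA
  consumes), with Manhattan available. The explanatory side of the
  dbRDA models uses one numeric column per category (the affinity
  values themselves), matching how selected variables are reported in
  the reference analyses; `affinityDistance()` exposes the
  distance-matrix reading for users who want it.
* Lineages never observed have undefined affinities and are excluded
  from affinity-based analyses, with warnings; zero-affinity rows are
  retained (flagged) in `categoryAffinity()` so bookkeeping stays
  aligned with the occurrence matrix.
* Negative neighbor-joining branch lengths are clamped to zero and
  counted in an attribute.
* The haplotype network is the union of all minimum spanning trees of
  the Hamming matrix (Kruskal by weight class over the union-find
  components accumulated from strictly lighter classes), plus any edge
  no longer than the longest MST edge plus `epsilon` (default 0). The
  published figures this reproduces show single-substitution edges with
  dots for missing intermediates, which is exactly an MSN rendering; the
  original network algorithm is not named, so MSN is a documented,
  fully testable stand-in, and median-joining is a non-goal.
* Every generator is a pure function of (configuration, seed); pipelines
  thread a single integer seed through permutations and starts, so reruns
  are bit-identical.

## Problem sizes used in validation

The shipped validation runs at: 200 seeds per scenario for the
power/specificity recovery of the environment and geography scenarios
(199 permutations each); 1000 simulated null datasets at 199 permutations
for calibration, for both RDA and dbRDA; 50 random datasets for the
dbRDA–RDA equivalence bound at 1e-9; 100 random trees against the
shortest-path patristic oracle; NJ recovery up to 50 tips; 10,000 sites
for the Jukes–Cantor closed-form comparison at 3 Monte-Carlo standard
errors. The acceptance script recomputes the headline quantities at 100
seeds per scenario and 500 null datasets.

## Known limitations

* The printed distance statistics of the deposited lineage sets (mean
  3.4/67 substitutions; maximum 15/191) can only be checked against the
  PANGAEA accession (doi:10.1594/PANGAEA.848399), which cannot be
  redistributed here; the corresponding check is present but requires the
  user to supply the FASTA files.
* Reported percentages in the source literature occasionally disagree
  with their own counts (6/67 printed as 9.8%); the package reports the
  count and count/length and does not attempt to reproduce inconsistent
  derived values.
* Exact reproduction of published permutation p-values is not claimed:
  the permutation scheme and count behind them are unstated, and the
  original Bayesian tree is not deposited.
* The NMDS stress uses the standard Kruskal stress-1 normalisation (sum
  of squared configuration distances in the denominator), the convention
  of the software family the reference analyses used.
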