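# lineageAffinity

Does the evolutionary relatedness of closely related diatom lineages track
the **environment** they live in, or the **geography** they were sampled
from? `lineageAffinity` implements the full inference chain used to answer
that question from lake sedimentary DNA (sedDNA): short *rbcL* fragments of
*Staurosira* lineages cloned from modern surface sediments of lakes spanning
the Siberian tundra–taiga treeline, and from the horizons of a
mid-Holocene sediment core.

The package is aimed at molecular ecologists and palaeo-geneticists who
work with small sets of closely related sequence types (intra/inter-specific
lineages) and presence/absence occurrence data, and who want the whole
path from raw clones to constrained-ordination inference to be scripted,
seeded and testable.

## What it computes

Given aligned lineage sequences, a phylogenetic tree with branch lengths,
and a binary lineage × sample occurrence matrix:

* **Sequence processing** — clone dereplication into sequence types;
  a stringent authenticity filter (a type must be seen in ≥ 2 clones from
  ≥ 2 independent PCRs) excluding polymerase-error variants; fragment
  trimming and collapsing (e.g. a 191-bp set trimmed to its nested 67-bp
  window); uncorrected pairwise nucleotide (Hamming) distances and their
  summaries.
* **Phylogenetics** — patristic distances
  `d(u,v) = Σ branch lengths on the u–v path`; a neighbor-joining builder
  for synthetic pipelines; minimum-spanning haplotype networks in which an
  observed pair at Hamming distance *d* is connected through *d − 1*
  inferred ("missing") haplotypes, annotated with vegetation-type
  proportions or *Larix* pollen affinity.
* **Affinity statistics** — the per-lineage *transect affinity* and
  *vegetation-type affinity*: the occupancy proportion of lineage *i* in
  category *c*,
  `A(i,c) = (# samples of c where i occurs) / (# samples of c)`,
  which corrects for unequal numbers of lakes per category; and the scalar
  *Larix* pollen affinity `LA(i) = Σ_s x_is p_s / Σ_s x_is`, the mean
  *Larix* percentage of the horizons a lineage occupies.
* **Ordination engine** (written from scratch, cross-checked against vegan
  in the test suite) — Bray–Curtis dissimilarity; NMDS minimising Kruskal
  stress-1 by majorization with isotonic regression; RDA with
  `R² = ‖HY‖²/‖Y‖²`, Ezekiel-adjusted R², pseudo-F and a row-permutation
  test; PCoA with Lingoes/Cailliez corrections; distance-based RDA (PCoA →
  RDA); and greedy forward selection with conditional permutation tests at
  p < 0.1.
* **Pipelines** — `runSpatial()` (NMDS + RDA + dbRDA of patristic
  distances vs transect/vegetation affinities), `runTemporal()` (dbRDA of
  core-lineage patristic distances vs *Larix* affinity), `runComparison()`
  (shared / modern-only / core-only lineage partition with near-matches at
  1–2 nucleotides), and `summarizeLakes()` (median/quartile lake tables).
* **Synthetic data** — a seeded generator for the whole study design:
  Yule trees, Jukes–Cantor sequence evolution
  (`p = ¾(1 − e^(−4μt/3))` per site per branch), Gaussian-niche occupancy
  of 21 lakes in 3 transects × 4 ordered vegetation types, a 20-horizon
  core with a declining *Larix* curve, and clone libraries with rare
  polymerase errors — switchable between environment-driven,
  geography-driven and null scenarios.

## Worked example

```r
library(lineageAffinity)

sim <- simulateDataset(simulationConfig(scenario = "environment", seed = 7))
sim$lineages
#> LineageSet 'simulated': 14 lineages x 67 bp
#>   ids: lineage_01, lineage_02, lineage_03, lineage_04, lineage_05, lineage_06 ...

res <- runSpatial(sim$occurrence, sim$sampleTable, sim$tree,
                  nPerm = 999, seed = 7)
res$table
#>                 data     explanatory_set                                   selected     R2   adjR2     P
#> 1         occurrence    transect dummies                                     (none) 0.0335 -0.0174 0.736
#> 2         occurrence  vegetation dummies vegetation_2 + vegetation_3 + vegetation_4 0.5255  0.4418 0.001
#> 3 patristic distance   transect affinity                                     (none) 0.0926  0.0170 0.288
#> 4 patristic distance vegetation affinity        vegetation_aff_4 + vegetation_aff_3 0.5429  0.4598 0.001
```

The table mirrors the structure of a constrained-ordination results table:
one row per test, with the forward-selected explanatory set, the model R²
and adjusted R², and the permutation p-value. Here the data were generated
under the environment scenario, and the analysis recovers exactly that
structure: lineage occurrences and patristic relatedness are significantly
explained by vegetation affinity (P = 0.001) while the transect
(geography) models select nothing (P = 0.74 / 0.29). The sample NMDS has
stress 0.075, i.e. the presence/absence structure is nearly planar.

The temporal analysis on the simulated core gives the matching down-core
result — relatedness tracks the *Larix* pollen gradient:

```r
tmp <- runTemporal(sim$core$occurrence, sim$core$sampleTable, sim$tree,
                   nPerm = 999, seed = 7)
tmp$table
#>                        data       explanatory_set       selected    R2 adjR2     P
#> 1 patristic distance (core) Larix pollen affinity larix_affinity 0.356 0.302 0.002
```

The lake-table summary reproduces printed reference values exactly
(median pH 7.09, median conductivity 40.7 µS/cm, median *Larix* 2.62 %):

```r
lakes <- readSampleTable(system.file("extdata", "treeline_lakes.tsv",
                                     package = "lineageAffinity"))
summarizeLakes(lakes)[, c("pH", "conductivity", "larix_pct")]
#>          pH conductivity larix_pct
#> median 7.09         40.7      2.62
#> q1     6.57         32.0      1.74
#> q3     7.38         59.0      3.53
```

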