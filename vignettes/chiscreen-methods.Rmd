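---
title: "Methods: complex heterozygosity screen analysis with chiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex heterozygosity screen analysis with chiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiscreen)
```

## The experimental design this package analyses

Complex haploinsufficiency (CHI) is the deleterious phenotype of a
diploid heterozygous for loss-of-function alleles of two different
genes. A CHI screen of the kind `chiscreen` analyses crosses a panel of
point-mutant *query alleles* of one gene — here, alanine-scan alleles of
yeast actin, each substituting a small cluster of charged surface
residues with alanine — against deletion alleles of a set of partner
genes, and scores each digenic heterozygote's growth defect on a
three-step scale: **1 = lethal, 2 = severe growth defect, 3 = mildly
reduced colony size**, with 0 meaning no interaction was observed.

Two facts make this data worth a dedicated analysis package. First, the
query alleles are all alleles of *one* gene, so their interaction
profiles can be compared directly: alleles that break the same
protein–protein interface should fail with the same partners. Second,
the mutated residues have known coordinates on the actin monomer and on
filament models, so profile similarity can be tested against physical
distance — including distances across the two kinds of subunit
interface of the two-start actin filament helix, the intrastrand
("stacked", long-pitch) contact and the interstrand ("backed") contact.

## Data model

`chi_matrix()` holds the allele × gene score matrix (integers 0–3,
rectangular, unique ids). Scores rank severity with 1 strongest, which
is the wrong orientation for similarity computations: clustering needs
the strongest interaction to carry the largest weight so that mild
scores sit nearest to non-interactions. `reverse_weights()` applies the
element-wise map `s -> 4 - s` on nonzero cells (1→3, 2→2, 3→1, 0→0).
This reversal is an involution: applying it twice restores the scores.

Allele annotations (`read_annotations()`, `act1_alleles()`) carry a
mutation specification string such as `"D363A,E364A"`, a phenotype
class and a surface-location class. Phenotype labels are normalised
case-insensitively into a closed vocabulary because class membership
drives summary statistics and must be deterministic. Residue numbers
follow mature-protein numbering and are used unchanged as PDB residue
sequence numbers.

## Screen statistics

Degrees count interacting partners; severity is ignored (a published
per-allele interaction count is a count, not a weighted sum).
`phenotype_class_summary()` reports per-class mean degrees at full
precision, with a one-decimal column for display. The bundled allele
table reproduces the familiar headline numbers:

```{r}
ann <- act1_alleles()
deg <- data.frame(id = ann$allele_id, degree = ann$interactions)
round(mean(deg$degree), 1)
phenotype_class_summary(deg, ann)[, c("phenotype", "n_alleles", "mean_degree_1dp")]
```

`pearson_with_ci()` is the generic degree–feature correlation: the
product-moment coefficient, a two-sided p from the t transform
`t = r sqrt(n-2)/sqrt(1-r^2)`, and a Fisher-z confidence interval. The
physiological/evolutionary feature compendium itself is external data
and out of scope; only the computation is provided.
`digenic_combinations(n)` is the `n(n-1)/2` count of digenic
combinations an individual with `n` loss-of-function alleles carries.

## Replicate validation

`build_standard()` defines the gold standard as the pairs called in at
least `min_support` replicates (default 2, "two or more screens");
`precision_recall()` scores an independent screen against it. A pair is
"called" if it was scored at all — severity plays no role here. The
evaluated screen is never part of standard construction.

## Two-way hierarchical clustering

Similarity between two weight profiles is **uncentered Pearson
correlation** — Pearson's formula without mean subtraction, i.e. the
cosine of the angle between the vectors. For sparse interaction
profiles this is the right choice because 0 is a true origin ("no
interaction"), not an arbitrary baseline; centering would let the many
zeros dominate the means. The companion distance is `1 - s`.

`average_linkage()` is an agglomerative UPGMA: at each step the two
closest clusters merge and inter-cluster distance is the unweighted
arithmetic mean of all cross-pair leaf distances. Numerical choices:

* **Tie-break**: ties in the minimum distance are broken by the
  smallest (row, column) position in the current cluster ordering, in
  which a merged cluster takes the position of its first member. This
  makes output deterministic across platforms.
* Merge heights under UPGMA are monotone non-decreasing (the linkage is
  reducible), so recorded join similarities `1 - height` never increase
  down the tree files.
* No row normalisation or log transform is applied — clustering
  operates on the reverse-weighted 0–3 matrix directly.
* All-zero rows and columns are dropped with a warning before
  similarity computation (the cosine of a zero vector is undefined; in
  the real screen 35 of the 238 genes interact with no query allele and
  have empty columns). By default genes are clustered on the
  interacting columns only.

`two_way_cluster()` clusters rows and columns independently;
`cut_clusters()` extracts k flat clusters by undoing the last k−1
merges, labelling clusters 1..k in dendrogram leaf order. The number of
allele clusters is a parameter (the reference analysis chose nine); no
automatic selection is attempted because the original cut criterion is
not recoverable.

Export (`write_cdt_gtr_atr()`) follows Cluster 3.0 conventions — CDT
with `GENE<i>X` row and `ARRY<j>X` column identifiers and the matrix
reordered to leaf order, GTR/ATR with one `NODE<s>X` line per merge —
so the result loads directly into Java TreeView. No heat-map rendering
is done in R; visualisation is delegated to TreeView.

## Structural mapping and distances

`read_pdb_calpha()` keeps Cα atoms only, first alternate location wins,
and insertion codes are rejected — determinism on real PDB dialects
beats completeness here. An allele maps to the Cα coordinates of its
substituted positions; alleles with *no* resolved residue are flagged
unusable and excluded from distance analysis (alleles with at least one
resolved residue participate).

`pair_distance()` measures the shortest straight-line Cα–Cα distance
between the two alleles' residue sets: on one subunit (`monomer`), or
across every declared subunit pair of a kind (`stacked`/`backed`) in
both orientations, returning the overall minimum — symmetric in the two
alleles by construction. Which chains of a deposited filament model
constitute stacked or backed neighbours is **explicit configuration**
(`filament_topology()`), never inferred from coordinates: deposited
models do not name their neighbour relations, and every downstream
number depends on the choice. For a 5-subunit long-pitch model the
natural declaration is stacked = (k, k+2) in helical numbering and
backed = (k, k+1).

## Profile similarity versus structural distance

`similarity_distance_correlation()` correlates the pairwise profile
similarity vector with the pairwise distance vector of one
configuration. Two p-values are reported:

* an analytic two-sided p from the t transform with `n_pairs - 2`
  degrees of freedom, and
* a **Mantel-style permutation p**: allele identities are permuted
  jointly — rows and columns of the distance relation are relabelled
  together, never the flattened pair vector independently — and the
  two-sided p counts permutations with `|r|` at least the observed
  `|r|`, with the +1 small-sample correction.

The permutation p is the one to trust: the `C(n,2)` pairwise
observations share alleles and are not independent, so the analytic p
overstates certainty. Both are reported because the reference analyses
in this field typically print the parametric-looking value. All tests
are two-sided; directionality belongs to interpretation. Alleles are
sorted canonically before the permutation loop so the result does not
depend on input order, and the seed is a required argument.

`region_groups()` merges the four surface classes into
exposed (front + top/bottom) versus obscured (back + side), excluding
ATP-cleft and unresolved alleles, and `rank_sum_test()` compares the
degree distributions: exact Wilcoxon null when both groups have ≤ 12
observations and no ties, otherwise the normal approximation with tie
and continuity corrections.

## The synthetic data generator

Real screen matrices of this kind are supplementary data and often
unavailable; every stage of the pipeline is therefore testable against
`synthetic_config()` + `generate_filament()` +
`plant_alleles_and_matrix()` + `generate_replicates()`, whose defaults
are the study conditions of the actin screen:

| parameter | default | meaning |
|---|---|---|
| `n_alleles`, `n_genes` | 32, 238 | screen dimensions |
| `k_clusters`, `genes_per_cluster` | 9, 22 | planted allele clusters and their gene sets |
| `p_signal`, `p_background` | 0.8, 0.02 | hit probability inside / outside the cluster |
| `severity_weights` | (0.25, 0.35, 0.40) | score 1/2/3 mix among hits; lethality is the rarest call |
| `rise_per_subunit`, `twist_per_subunit` | 27.5 Å, −166.7° | actin-like helix parameters |
| `helix_radius`, `subunit_radius` | 30 Å, 30 Å | subunit-centre helix and subunit size |
| `residues_per_subunit` | 375 | actin-like chain length |
| `patch_radius` | 4 Å | capture radius of an interface mutation site |
| `detection_prob`, `replicate_fp_rate` | 0.7, 0.002 | per-replicate detection and false-call rates |
| `n_replicates` | 4 | replicates behind the gold standard |

`detection_prob = 0.7` with a ≥2-of-4 standard gives expected precision
≈ 90% and recall ≈ 70% for an independent screen — the regime the
validation machinery is meant to operate in.

### Planting a stacked-specific spatial signal

The geometric design goal is strict: profile clusters must predict
*stacked* proximity while monomer and backed distances stay
uninformative, so that the analysis pipeline — not the generator — is
what distinguishes the three configurations. An early design in which
each cluster's alleles shared a single surface patch fails this goal
immediately: a shared patch makes the *monomer* distances of
same-cluster pairs tiny, planting a strong signal in every
configuration at once.

The design used instead exploits the fact that all distances are
minima over residue pairs. Every synthetic allele mutates one residue
near each interface pole of the subunit: one on the ring facing the
stacked neighbour above, one on the ring facing the neighbour below
(the filament generator enriches the residue layout on these two
interface bands, as real subunit-contact surfaces are enriched in
interface residues). Within a cluster the alleles form a **chain of
stacked contacts**: the top-ring azimuth of allele j is chosen
uniformly at random, and its exact contact point on the stacked
neighbour's bottom ring becomes the bottom site of allele j+1. All
remaining azimuths are independent and uniform.

Consequences, by configuration:

* **stacked** — consecutive cluster members touch across the interface
  (a few Å apart), far below the typical minimum for unrelated pairs;
* **monomer** and **backed** — the distance minimum is always realised
  by combinations of azimuths that are iid uniform for *every* pair,
  within-cluster or not, so these distances are draws from one and the
  same distribution regardless of cluster membership. The neutrality is
  distributional, by construction, not a numerical cancellation.

The helix radius default (30 Å) was fixed after a geometry scan: with
the two strands well separated laterally, the cross-pole distance terms
correlated by the contact construction sit far from the backed minimum
and leave no residual backed signal. Under the frozen defaults, across
seeds 1–100: cluster recovery at k = 9 reaches adjusted Rand index
≥ 0.9 in 100% of runs, the stacked permutation correlation is negative
and significant (p < 0.05) in 99%, while monomer and backed remain
non-significant in 97% and 93% of runs respectively.

### What the generator does and does not emulate

It emulates the screen's dimensionality, score mix, replicate
detection behaviour, the existence of noninteracting genes, and a
filament with realistic rise/twist and distance scales. It does **not**
emulate colony-growth biology (plate or batch effects, FOA
counter-selection, temperature dependence), real protein shapes
(subunits are spheres), allele-specific interaction breadth (planted
clusters are exchangeable), or annotation judgment calls. Passing
recovery tests on synthetic data therefore demonstrates the
correctness of the computations, not that real screens will show the
same effect sizes.

## Problem sizes and determinism

The test suite runs the full 32 × 238 default configuration for the
recovery and specificity properties (100 seeded replicates, 499
permutations per test) and a reduced 16 × 80, 5-subunit configuration
for pipeline smoke and determinism tests; oracle comparisons use 200
random instances of up to 8 leaves (UPGMA) or 6 × 6 point sets
(distances). All generators and permutation tests are pure functions of
(configuration, seed); the pipeline writes only deterministic text, so
two runs with the same inputs and seed are byte-identical.

## Known limitations

* The published full interaction matrix is supplementary data; the
  package ships only the per-allele annotation table, so the headline
  structural correlation of the original study (r = −0.1424) is not
  re-derivable exactly — the synthetic recovery properties stand in
  for it, and the published aggregate counts it *does* ship reproduce
  (precision 90%, recall 69%, class means 48.2 and 29.6, the 17
  back/side alleles, medians 40 vs 13 with rank-sum p ≈ 0.024).
* Surface-location classes are taken from the annotation table, not
  computed from solvent accessibility.
* UPGMA with deterministic tie-breaking can differ from other
  implementations on tied dissimilarities; ties are measure-zero for
  continuous similarities but common in tiny hand-made examples.
* The yeast residue numbering is applied directly to muscle-actin
  filament models without alignment offsetting; a per-position offset
  map can be supplied where that matters.
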