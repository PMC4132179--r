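# chiscreen

Analysis of **complex heterozygosity (CHI) interaction screens**: diploid
genetic screens in which point-mutant query alleles of one gene (here,
alanine-scan alleles of yeast actin) are crossed against deletion alleles
of many partner genes and each digenic heterozygote is scored for growth
defects (1 = lethal, 2 = severe, 3 = mild; 0 = no interaction).

The package is for geneticists and structural biologists who want to go
from a scored allele × gene matrix to:

* **degree statistics** — interaction counts per allele/gene, phenotype
  class summaries, degree–feature correlations
  (`r` with Fisher-z CI and t-based p), and the digenic combinatorics
  `n(n-1)/2` of carrying `n` loss-of-function alleles;
* **replicate validation** — a gold standard of pairs supported by ≥ 2
  of k replicate screens, and precision/recall of an independent screen
  against it;
* **two-way hierarchical clustering** of interaction profiles with
  *uncentered Pearson* similarity (cosine; no mean-centering, so
  "no interaction" is a true origin) and *average linkage* (UPGMA),
  after reversing score weights (`s -> 4 - s`) so the strongest defect
  carries the largest weight — with Cluster 3.0 / Java TreeView
  compatible CDT/GTR/ATR export;
* **structural mapping** — mutated residues on monomer and filament
  models (PDB Cα), minimum Cα–Cα distances between allele pairs in
  monomer, intrastrand *stacked* and interstrand *backed* subunit
  configurations (declared via an explicit filament topology), and
  per-residue degree attributes for molecular viewers;
* **profile–structure correlation** — Pearson correlation between
  profile similarity and structural distance with an analytic p and a
  Mantel-style label-permutation p, plus the Wilcoxon rank-sum contrast
  between exposed (front/top/bottom) and obscured (back/side) surface
  regions;
* a **synthetic-data generator** that plants allele clusters on an
  idealised helical filament (chained stacked contacts) so the entire
  pipeline is testable end to end without the unpublished screen data.

## Worked example

```r
library(chiscreen)

## published allele table bundled with the package
ann <- act1_alleles()
deg <- data.frame(id = ann$allele_id, degree = ann$interactions)
round(mean(deg$degree), 1)
#> [1] 29.6
s <- phenotype_class_summary(deg, ann)
s[s$phenotype == "lethal partial dominant", c("phenotype", "n_alleles", "mean_degree")]
#>                 phenotype n_alleles mean_degree
#> 2 lethal partial dominant         5        48.2

grp <- region_groups(ann)
rank_sum_test(deg$degree[match(grp$front_top_bottom, deg$id)],
              deg$degree[match(grp$back_side, deg$id)])
#> rank-sum test (normal approximation): medians 40 vs 13, rank-sum A = 256, p = 0.02376
```

The exposed surface regions (front and top/bottom, 13 alleles, median
40 interactions) are significantly more interactive than the obscured
back/side regions (17 alleles, median 13), consistent with exposed
surfaces mediating more protein–protein contacts.

A full synthetic screen, end to end:

```r
paths <- simulate_screen("sim", synthetic_config(), seed = 4)
res <- run_chi_pipeline(paths$matrix, paths$annotations, paths$pdb,
                        paths$topology, paths$replicates, paths$independent,
                        out_dir = "out", k_clusters = 9, seed = 4)
cat(readLines(res$summary_path)[6:11], sep = "\n")
#> precision  0.904665
#> recall     0.688272
#> n_standard 648
#> k_clusters 9
#> mantel_stacked_r -0.174511
#> mantel_stacked_p_permutation 0.002
```

Here the replicate-based standard recovers the planted detection regime
(precision ≈ 90%, recall ≈ 69%), and profile similarity correlates
negatively with stacked-dimer distance (r ≈ −0.17, permutation
p = 0.002) while monomer and backed configurations stay non-significant
— the planted geometry is detected only where it was planted. The
`out/` directory also contains the clustered matrix as
`clustered.cdt/.gtr/.atr` (loadable in Java TreeView), the pairwise
similarity/distance table, and a molecular-viewer attribute file
colouring residues by interaction degree.

A thin command-line wrapper is installed at
`inst/scripts/chiscreen-pipeline.R`
(`simulate`, `run`, `combinations` subcommands).

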