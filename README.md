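# dcoloc — subcellular transcript colocalization statistics

`dcoloc` is an R toolkit for analyzing single-molecule resolution spatial
transcriptomics data (MERFISH and similar): tables of per-transcript
coordinates grouped by cell. It asks a question that whole-cell expression
analysis cannot: *which gene pairs place their transcripts near each other
inside cells?* Such proximity can reflect RNA–RNA interaction, shared
binding partners, or co-localization to subcellular structures, and it is
invisible to co-expression analysis.

The toolkit is built around two statistics:

* **Proximal-pair (PP) test** — per cell: for gene pair $(g_i, g_j)$ with
  $t_i, t_j$ transcripts, the number $K$ of cross-gene transcript pairs
  within distance $d$ is tested against $\mathrm{Binomial}(T = t_i t_j,\ p)$,
  where $p$ is the cell's own background proximity rate, estimated from all
  transcript pairs regardless of gene identity. Supports multi-plane (3D)
  data and an intra-nucleus mode.
* **Conditional Poisson-Binomial (CPB) test** — across cells: the number of
  cells where the pair fired is tested against an exact Poisson-Binomial
  null whose per-cell probabilities
  $p_{ij}^c = 1 - (1 - \Pi_{ij})^{N_c}$, with
  $\Pi_{ij} = z_i z_j / \sum_{i<j} z_i z_j$, de-emphasize pairs of
  promiscuously proximal (usually highly expressed) genes. Significant
  pairs form the *d-colocalization map*.

Around the core sit: subcellular region annotation (nucleus / peri-nucleus
/ cytosol / cell periphery), permutation and blank-probe false-positive
estimation, cell-type specificity categories built on a conditional
(multivariate) hypergeometric test, a spatial-modulation likelihood-ratio
test on a cell neighbor graph with a permutation max-statistic threshold,
gene-module discovery by hierarchical clustering (GCC) and frequent
clique/edge-set mining (FSM), and a synthetic-data generator with planted
ground truth that powers the entire test suite.

## Worked example

Simulate a 150-cell, 30-gene dataset (plus 3 blank probes) with two planted
proximal pairs, then run the core workflow:

```r
library(dcoloc)

planted <- data.frame(gene_a = c("g001", "g003"), gene_b = c("g002", "g004"),
                      rho = 0.5, sigma = 0.5)
sim <- simulate_dataset(sim_config(n_cells = 150, n_genes = 30, n_blanks = 3,
                                   cell_radius_mean = 20,
                                   planted_pairs = planted, seed = 8))

tab <- assign_regions(sim$transcripts, sim$geometry)   # Nuc/PN/Cyt/CP labels
ind <- pp_test_dataset(tab, d = 2, alpha_pp = 0.01)    # per-cell PP test
map <- annotate_map(cpb_test(ind), ind)                # d-colocalization map
head(map, 5)
#>   gene_a gene_b support n_coexpressed_cells   pvalue primary_region secondary_region
#> 1   g001   g002      94                 150 8.43e-65             CP              Cyt
#> 2   g003   g004     100                 150 6.44e-64             CP               PN
#> 3   g012   g027       4                 150 4.41e-03             CP              Cyt
#> 4   g009   g023       2                  75 7.61e-03            Cyt               PN
#> 5   g012   g021       3                 150 7.95e-03             CP              Cyt
```

The two planted pairs dominate the map: each was a significant proximal
pair in ~100 of 150 cells (`support`), with Poisson-Binomial p-values
vastly below anything a background pair reaches. The nearest background
pair has support 4 and p ≈ 4e-3, which does not survive the map threshold
chosen next.

False-positive control by within-cell label permutation and by the blank
probes:

```r
perm <- permute_gene_labels(tab, seed = 9)
pmap <- cpb_test(pp_test_dataset(perm, d = 2, alpha_pp = 0.01))
estimate_fpr(map, pmap, thresholds = 1e-3)
#>   threshold n_real n_permuted fpr
#> 1     0.001      2          0   0

blank_probe_fpr(map, sprintf("Blank-%d", 1:3), threshold = 1e-3)$observed
#> [1] 0
```

At the `1e-3` threshold the real map keeps exactly the two planted pairs,
the permuted map keeps nothing (FPR 0), and no blank-probe pair is
significant (17.6% would be expected if significant pairs were random).

Downstream modules take the same objects: `categorize_pairs()` for
cell-type specificity (categories 1–3), `spatial_modulation_scan()` for
tissue-level clustering of supporting cells, `gcc_cluster()` and
`fsm_mine()` for gene modules, `run_pipeline()` to orchestrate everything
from one YAML config (see the methods vignette in `vignettes/`), and
`inst/cli/dcoloc` as a shell entry point.

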