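---
title: "Statistical models and design choices in dcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models and design choices in dcoloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcoloc)
```

`dcoloc` analyzes single-molecule resolution spatial transcriptomics data —
tables of per-transcript coordinates with cell assignments, as produced by
MERFISH and related technologies — for *subcellular colocalization* of gene
pairs. This vignette explains the statistical models, the tunable parameters
and their defaults, the synthetic-data generator used throughout the test
suite, and the design decisions made where the methodology left genuine
choices open.

## The proximal-pair (PP) test

Within one cell, a gene pair $(g_i, g_j)$ is a *proximal pair* at scale $d$
if its transcripts lie within distance $d$ of each other more often than
expected from the cell's own spatial texture. With $t_i$ and $t_j$
transcripts of the two genes, $T = t_i t_j$ cross-gene transcript pairs are
possible; $K$ of them are observed at distance $\le d$. The null probability
$p$ of a random transcript pair being proximal is estimated empirically from
*all* unordered transcript pairs in the cell, regardless of gene identity:

$$ p = \frac{\#\{(t, t'): \lVert t - t'\rVert \le d\}}{\binom{N}{2}}, \qquad
   \text{p-value}(g_i, g_j) = P\!\left(X \ge K \mid X \sim
   \mathrm{Bin}(T, p)\right). $$

Because $p$ is re-estimated per cell, differences in cell size, shape and
RNA density are absorbed into the null. The binomial survival probability is
computed exactly (`pbinom`); no normal approximation is used, which is what
makes the enumeration oracles in the test suite exact.

Conventions worth stating explicitly:

* "within distance $d$" is closed ($\le d$). Coordinates are continuous, so
  the boundary has measure zero; fixing the convention makes counting tests
  exact.
* Same-gene transcript pairs count toward the null estimate $p$ (it is
  estimated "regardless of gene identities") but never toward $K$; a
  transcript is never paired with itself.
* The pair universe is unordered distinct gene pairs $i < j$.
* $K$ counting uses a grid-hash fixed-radius neighbor search (Rcpp) with
  expected linear cost; an all-pairs distance-matrix scan is retained as the
  `method = "naive"` oracle and the two are asserted identical in the tests.
* Degenerate cells: with $p = 0$ and $K = 0$ the p-value is 1; $p = 0$ with
  $K > 0$ yields 0 with a warning (it indicates an inconsistent distance
  computation upstream).

**Multi-plane data (PP-3D).** When transcripts carry a z-plane index, planes
are treated as independent, identically distributed replicates of the cell:
pairs are never formed across planes, $K = \sum_z K_z$ and $T = \sum_z T_z$,
and the null is pooled as the transcript-count-weighted mean
$p = \sum_z l_z p_z / \sum_z l_z$ with $l_z$ the number of transcripts in
plane $z$. Planes with fewer than two transcripts are skipped. A sum of
binomials with a shared parameter is again binomial, so the p-value keeps
its exact form.

**Intra-nucleus mode.** `nucleus_only = TRUE` restricts both the tested
transcripts and the null estimation to the subnuclear compartment (region
`Nuc`, plus `PN` transcripts located inside the nucleus), for probing
colocalization within the nucleus specifically.

## Aggregation across cells: UPB and CPB

A pair detected in one cell is weak evidence; the interesting pairs are
*d-colocalized* — proximal in significantly many cells. Let
$X_{ij}^c \in \{0,1\}$ indicate that $(g_i,g_j)$ passed the PP test in cell
$c$ at level `alpha_pp`, and let $N_c = \sum_{i<j} X_{ij}^c$.

The *unconditional* test (UPB) assumes every expressed pair in a cell is
equally likely to fire: $X_{ij}^c \sim \mathrm{Ber}(p_0^c)$ with $p_0^c =
N_c / \#\{\text{expressed pairs in } c\}$ ("expressed" means at least one
transcript of each gene, configurable). The support $\sum_c X_{ij}^c$ then
follows a Poisson-Binomial distribution over the cells where both genes are
expressed, and the p-value is its exact upper tail, computed by
dynamic-programming convolution in `poisson_binomial_sf()`.

The *conditional* test (CPB) drops the exchangeability assumption: genes
that are promiscuously proximal everywhere (typically the highly expressed
ones) should not dominate the map. With $z_i$ the total number of
proximal-pair events involving gene $i$ across all cells, the prior that a
detected event is pair $(i,j)$ is

$$ \Pi_{ij} = \frac{z_i z_j}{\sum_{i<j} z_i z_j}, \qquad
   p_{ij}^c = 1 - (1 - \Pi_{ij})^{N_c}, $$

i.e. the chance that at least one of the $N_c$ events in cell $c$ is
$(i,j)$ under the prior. High-$z$ genes get large $\Pi$, hence large
$p_{ij}^c$, hence need far more supporting cells to reach significance —
the abundance correction that the acceptance suite verifies with the
inflated-gene experiment (CPB demotes a 10x-inflated non-interacting gene's
pairs relative to UPB).

Two choices here were genuinely open:

* The Poisson-Binomial convolution runs only over cells where both genes
  are expressed; unexpressed cells contribute neither support nor
  probability mass. The estimator $p_0^c$ is itself expression-aware, and a
  pair cannot fire without expression, so including those cells would
  deflate the null and anti-conservatively reward widely expressed pairs.
* $z_i$ is estimated from the same indicator matrix being tested. For pairs
  of rarely-proximal genes the prior is therefore noisy and small, and a
  handful of chance co-firings can reach small p-values. This is intrinsic
  to the conditional design; it is why map-level significance should be
  chosen by permutation FPR (see below) rather than by a fixed universal
  threshold. P-values are floored at `1e-300`.

Ranked outputs break ties by p-value, then support (descending), then
lexicographic gene names, so all orderings are deterministic.

## Region annotation

With cell and nucleus boundaries available, each transcript gets one of four
labels forming a partition: a peri-nuclear band `PN` of half-width 2.5 µm on
*either side* of the nuclear membrane (taking precedence over the regions it
straddles), `Nuc` inside the nucleus beyond the band, `CP` within 4 µm of
the cell membrane, and `Cyt` elsewhere. The defaults follow the calibration
that ~43% of nuclear transcripts fall in the band and ~35% of cytosolic
transcripts fall in the periphery on reference data; both widths are
parameters (`pn_halfwidth`, `cp_width`). One 2D boundary per cell applies to
all z-planes, matching how segmentation masks are usually exported.
Transcripts outside their cell boundary (segmentation noise) are labeled by
the nearest region with a warning.

A proximal transcript pair whose two members lie in different regions
contributes weight 1/2 to each member's region, so per-pair region tallies
always sum to $K$. A pair's *primary* and *secondary* regions are the two
largest tallies aggregated over cells, with ties broken by the fixed order
`Nuc > PN > Cyt > CP` (logged when it fires).

## False-positive control

Two complementary diagnostics:

* **Permutation FPR**: gene labels are shuffled within each cell
  (`permute_gene_labels()`), preserving every cell's spatial texture and
  per-gene counts while destroying gene-gene relationships. The FPR at a
  threshold is the ratio of detections on permuted data to detections on
  real data. This is the recommended way to pick the map threshold
  (`alpha_cpb`); defaults of `1e-3` (cell-line-like panels) and `1e-5`
  (tissue-like panels) reflect thresholds that achieved ~1% FPR at the
  scales those data were analyzed.
* **Blank probes**: control barcodes matching no real RNA. Any significant
  pair involving one is a known false positive; `blank_probe_fpr()` reports
  the observed fraction against the closed-form expectation
  $1 - \binom{n-b}{2}/\binom{n}{2}$ for $b$ blanks in an $n$-gene panel.
  Blanks are deliberately treated as ordinary genes by every test.

## Cell-type specificity

For a pair significant in the map, let $U$ be all cells, $M$ the cells of
one type, $O$ the cells where the pair fired, and $E$ the $|M|$ cells with
the highest expression of one of the genes (ties broken by cell id). The
association of $O$ with $M$ is an upper-tail hypergeometric test,
Bonferroni-corrected over (pairs x types). If significant, the association
is re-tested *conditional* on $E$: the probability that a random set of size
$|O|$ with the observed overlap $\alpha = |E \cap O|$ reaches
$\lambda = |M \cap O|$, given $\gamma = |M \cap E|$ — a multivariate
hypergeometric tail over the partition $\{M \cap E, M \setminus E,
E \setminus M, \text{rest}\}$, implemented as the explicit double sum with
log-binomial coefficients and verified against exhaustive enumeration.

Categories: **3** — no type association; **2** — associated, both
conditional tests (conditioning on each gene's $E$ in turn) significant and
neither gene among the type's top-10 markers, i.e. specificity beyond
either gene's expression; **1** — associated but explainable by expression
or marker status. Note the stringent class is labeled 2 here; a
`legacy_labels` flag swaps the 1/2 labels for compatibility with the
alternative numbering that appears in some descriptions of this scheme.
Marker genes are defined per type as the top `top_k = 10` genes by the
$E$-vs-$M$ hypergeometric association. Two-way specificity questions (e.g.
inhibitory vs excitatory only) are supported by restricting $U$ to the
union of the two types (`restrict_types`).

## Spatial modulation

Whether the cells supporting a pair cluster in the tissue is tested with a
likelihood ratio. Cells are nodes of a fixed-radius neighbor graph (100 µm
default). With $s_c$ the pair's indicator in cell $c$ and $p^{local}_c$ the
fraction of $c$'s neighbors with $s = 1$:

$$ H_0: s_c \sim \mathrm{Ber}(p^{global}), \qquad
   H_1: s_c \sim \mathrm{Ber}\!\left(w\, p^{local}_c +
   (1-w)\, p^{global}\right), \quad w \in [0,1]. $$

$H_0$'s MLE is the overall fraction; $H_1$ is maximized over
$(w, p^{global})$ — both free parameters — by bounded L-BFGS-B from four
multistarts at $(w, p^{global}) \in \{0.1, 0.9\}^2$, because the likelihood
can be multimodal. Per-cell success probabilities are clamped to
$[10^{-9}, 1 - 10^{-9}]$; cells without neighbors fall back to
$p^{global}$, nulling their influence on $w$. The tests verify the
optimizer against a dense two-stage 200x200 grid search to within $10^{-6}$
log-units, and that under iid labels the fitted $w$ concentrates near 0.

Significance uses a permutation max-statistic: each scanned pair's $s$
vector is permuted across all cells `n_perm` times (10 by default; the
count is configurable since no canonical value exists), and the threshold
is the largest LLR seen anywhere on permuted data. This controls the
family-wise error over the scanned pairs by construction.

## Module discovery

**GCC** clusters the $n \times n$ matrix of $-\log_{10}(p + 10^{-64})$ CPB
p-values (the pseudocount absorbs floored p-values; the base is irrelevant —
Ward merges are invariant to uniform scaling, which the tests assert) with
Ward linkage on Euclidean row distances. The dendrogram needs a cut rule:
we cut to `n_clusters` flat clusters and report as modules those whose
internal significant-pair density reaches `min_density` (default 0.7, below
the ~0.82–0.91 internal densities typical of clean modules, above anything
a null background produces).

**FSM** finds gene networks whose *every* edge is a proximal pair
simultaneously in many cells. Since a gene occurs at most once per cell
graph, general subgraph isomorphism is unnecessary: mining reduces exactly
to frequent edge-set (itemset) mining with an Apriori join, plus a
connectivity or clique constraint — `fsm_mine()` implements both, reports
maximal frequent results, and `support_histogram()` tabulates the support
of every $k$-clique. The per-cell edge threshold (`alpha = 0.05` by
default) is deliberately looser than `alpha_pp`: network support requires
several pairs to fire at once, so a stricter edge threshold empties the
search space quickly.

## The synthetic-data generator

`simulate_dataset()` produces datasets with known ground truth: cells as
discs on a jittered grid (disc geometry gives closed-form region distances
for the test oracles; polygon boundaries are exercised separately through a
fixed irregular-polygon fixture), a concentric nucleus (radius fraction
0.5), per-cell totals log-normal around `mean_transcripts = 400` (size
spread `sdlog = 0.3`, within the 10²–10³ per-cell range typical of targeted
panels), relative gene abundances log-normal (`sdlog = 1`, spanning the
orders of magnitude real panels show), optional blanks at reduced
abundance, and uniform splitting of transcripts across z-planes (matching
the iid-plane assumption of the 3D test).

A planted pair $(a, b)$ with rate $\rho$ and scale $\sigma$ relocates, in
each cell, a Binomial($t$, $\rho$) subset of the rarer gene's transcripts
to a uniformly chosen partner transcript plus a displacement of half-normal
length (scale $\sigma$) in a uniform direction, in the partner's z-plane —
so planted partner distances are half-normal by construction, which the
suite checks with a KS test. Genes named in `planted_pairs` receive the
panel-mean abundance (unless overridden via `abundance_mult`): a planted
interaction on a gene whose abundance draw is near zero would not
constitute ground truth at all. Hotspot discs (`rho` inside, `rho_out`
outside) and per-type restriction (`cell_type` column) modulate $\rho$
spatially and by cell type. Blanks are always background. One global RNG
stream per dataset makes every output a pure function of the configuration.

What the generator does *not* emulate: optical noise, barcode
misidentification and crosstalk, nuclear substructure, irregular cell
shapes, 3D-varying boundaries, and spatially correlated cell-type layouts.
Passing the planted-signal tests therefore demonstrates correctness of the
statistics under the stated generative model, not robustness to every
artifact of real imaging data.

## Problem sizes and numerical choices

The test and acceptance workloads use 100–400 cells, 15–50 genes and ~400
transcripts per cell — small enough for the exact oracles (full $2^m$
enumeration for the Poisson-Binomial, exhaustive set enumeration for the
conditional hypergeometric, all-pairs distance scans, dense grid searches)
to run alongside the fast paths, while large enough that the planted-signal
and calibration properties are sharp. The same code paths scale to full
datasets: the neighbor search is linear in transcripts for bounded density,
and the Poisson-Binomial DP is quadratic in the cell count per pair.

Other numerical conventions: exact binomial/hypergeometric tails
throughout (`pbinom`, `phyper`); Benjamini–Hochberg is the only built-in
multiple-testing correction besides the Bonferroni step of the cell-type
scan; p-values floored at `1e-300`; all random procedures take explicit
seeds and restore the caller's RNG state.

## Known limitations

* The CPB prior $\Pi_{ij}$ is a point estimate; for genes with very few
  proximal events it is noisy, and isolated false detections at extreme
  thresholds are possible on pure-null data. Use the permutation FPR to set
  thresholds, as the workflow does.
* Region annotation assumes one 2D boundary per cell across z-planes.
* The spatial-modulation permutation threshold is a max-statistic over the
  scanned pairs; with very few permutations it is conservative, with many
  pairs it can be dominated by a single noisy pair.
* `filter_cells` and the PP preconditions silently drop cells (with a
  logged count); downstream indicator matrices contain only the retained
  cells.
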