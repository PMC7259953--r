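---
title: "Methods: single-cell heterogeneity analysis of yeast carbon shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell heterogeneity analysis of yeast carbon shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastlag)
```

## The analysis problem

Isogenic yeast cells shifted from glucose to maltose arrest growth (lag
phase) for durations that vary from hours to never-resuming. Droplet
scRNA-seq of such populations yields a genes × cells matrix of UMI counts,
plus side data: a bulk RNA-seq profile for validating the quantification,
and time-lapse lag-time measurements of micro-colonies (small groups of
cells descended from one founder). `yeastlag` implements the analysis
chain for this setting: quality control, normalization, marker-based and
unsupervised subpopulation discovery, differential expression,
co-expression module detection, pseudobulk–bulk concordance, and a test
for whether genealogically related cells behave more similarly than the
population at large.

This vignette explains each model, its assumptions and parameters, the
synthetic data generator used to test everything, and the design choices
made where the design was genuinely open.

## Stage models and parameters

### Experimental design arithmetic

`expected_cells()` maps post-dilution cell concentrations (cells/mL) to
expected recovered cells as
$\sum_i w_i \, c_i / d$ with mixing weights $w$ and a recovery divisor
$d = 100$. The divisor encodes the consistent concentration→expected
mapping of droplet loading tables (2.15×10⁵ cells/mL → 2150 cells); it is
exposed as a parameter rather than derived from loading volume and an
assumed capture rate, because only the outcome pattern of the mapping is
fixed by the protocol. Integer reports round half away from zero.

### Quality control

`cell_stats()` computes per cell the number of detected genes
(count > 0), total UMIs, and the mitochondrial percentage
$100 \cdot \sum_{g \in \text{mito}} n_{gc} / \sum_g n_{gc}$ (defined as 0
for empty columns). Mitochondrial genes are flagged by id prefix
(default `"Q0"`, the yeast mitochondrial systematic names) or an explicit
flag vector. `apply_qc()` removes cells *strictly above* either maximum —
"the maximum was set to X" keeps boundary cells at exactly X:

* `max_genes_detected` — doublet proxy; 2000 for glucose-grown and mixed
  samples, 1500 for lag samples in the experiment this emulates.
* `max_mito_pct` — damaged-cell proxy, on the percent scale by default
  (0.2 means 0.2%). Because thresholds quoted without units admit a
  fraction reading (0.2 meaning 20%), `mito_scale = "fraction"` switches
  the interpretation; percent is the default because the companion
  thresholds (0.5, 1.5) are implausible as fractions.

No minimum-gene bound is applied: empty-droplet removal belongs to the
upstream barcode caller, and only maxima are part of this stage's
contract. Filtering is monotone in both thresholds and idempotent (both
property-tested).

### Normalization

`log_normalize()` computes
$x_{gc} = \ln\!\left(1 + s\, n_{gc} / N_c\right)$ with scale factor
$s = 10^4$ (the customary default; configurable) and $N_c$ the cell's
total UMIs. Zero-total cells are retained as zero columns — dropping
cells is QC's job. Two exact consequences are used as test invariants:
$\sum_g \exp(x_{gc}) - 1 = s$ for every nonzero cell, and within-cell
rank order of counts is preserved.

### Pseudobulk–bulk concordance

`pseudobulk()` sums UMIs per gene; `concordance_r2()` joins the totals to
a bulk fpkm profile by exact gene id, transforms both sides as
$\log_{10}(\cdot + 0.1)$, and reports R² as the squared Pearson
correlation. The same pseudo-count 0.1 is applied to both axes for
symmetry (an undetected gene sits at $\log_{10} 0.1 = -1$). "Detected"
means strictly positive raw value. Genes detected in bulk but not in the
single-cell data are excluded from the fit (they reflect capture failure,
not quantification error) and counted as `n_bulk_only`; single-cell-only
genes stay in. Both inclusion rules are computable and the result records
which produced the headline number. The log base is configurable but
irrelevant: Pearson correlation is invariant under affine axis rescaling,
which also makes R² insensitive to overall fpkm scaling — up to the fixed
pseudo-count, which is why the synthetic bulk generator keeps the
pseudobulk scale by default.

### Marker classification

`classify_by_markers()` calls a cell positive when its raw UMI count
summed over the panel reaches `min_transcripts` (default 2). Raw counts
are used deliberately: the rule is a transcript-count rule and must not
depend on library-size scaling. The summed reading ("at least two
transcripts of the marker genes") is the default; because a per-gene
reading is also defensible, `mode = "any"` requires a single gene to
reach the threshold on its own. The default panel in examples is
MAL11/MAL12/MAL31/MAL32/IMA1 plus the glucose-repressed HXK1 — genes
expressed during maltose growth and silenced by glucose repression.

### Differential expression

`differential_expression()` tests each gene between two cell groups with
the package's Mann–Whitney rank-sum test (`rank_sum_test()`):

* mid-rank tie handling; U counts x-over-y wins with ties as ½;
* exact p from the null U distribution when $n_1 + n_2 \le 12$ with no
  ties; otherwise a normal approximation with tie correction
  $\sigma^2 = \frac{n_1 n_2}{12}\left[(n+1) - \sum_t (t^3 - t)/(n(n-1))\right]$
  and continuity correction. The test suite verifies the exact branch
  against full enumeration over all $\binom{n}{n_1}$ rank assignments and
  the approximate branch against the reference implementation.

Genes are pre-filtered to those expressed (count > 0) in at least
`min_expressing_fraction` (default 0.1) of one group; set 0 to test all.
Fold changes are computed on de-logged normalized means,
$\log_2\!\frac{\bar a + 0.01}{\bar b + 0.01}$, with the pseudo 0.01
guarding empty means. Significance requires Benjamini–Hochberg adjusted
p ≤ 0.05 *and* $|\log_2 FC| \ge 0.25$ — BH rather than Bonferroni because
the contract is a false-discovery-rate threshold. The log2 scale for the
fold-change gate is fixed by this package; direction is reported
separately from the two-sided p.

One calibration subtlety the test suite encodes: planting one-directional
effects in a simulation changes library sizes, and per-cell normalization
then shifts every null gene's normalized values compositionally —
inflating false positives that measure the normalization, not the test.
The calibration suite therefore plants direction-balanced effects (half
up in each group), under which the empirical FDR of the significant set
is verified ≤ 0.10 with 10% of genes at a 1.5× effect (2000 genes, 200
cells per group).

### Co-expression network

`build_network()` applies the filter cascade in a fixed order: (1) drop
genes with fewer than `min_total_umi = 10` raw UMIs across cells; (2)
Pearson-correlate all remaining gene pairs across cells on normalized
values, with two-sided p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df; (3) Bonferroni-adjust over all
unordered pairs among UMI-passing genes — the most conservative natural
family, since the published procedure does not state one; (4) call an
edge significant iff $|r| \ge 0.1$ and adjusted p ≤ 0.05; (5) drop genes
with fewer than `min_partners = 7` significant partners — by default in a
single pass with degrees frozen on the pre-prune set (`pruning =
"iterative"` recomputes to a fixed point, since the published order of
operations is unstated; iterative retains a subset of single-pass); (6)
zero the correlation diagonal; (7) cluster the retained correlation rows
into `n_modules` (default 6, the published module count) by agglomerative
clustering on Euclidean distances between correlation rows. The source
material names both k-means and hierarchical clustering for this step;
both are offered (`cluster_method`), hierarchical (average linkage) being
the default as the text's reading. Zero-variance genes get r = 0, p = 1
and never form edges. An empty surviving set is a logged empty network,
not an error. Module evaluation uses label-invariant scores
(`best_match_jaccard()`, `adjusted_rand_index()`).

### Subpopulation discovery

`cluster_cells()` replaces the published shared-nearest-neighbor graph
clustering (tuned via a resolution knob) with PCA + k-means at explicit
k — a documented simplification, not a re-implementation: the analysis
goal (recovering subpopulations such as the two lag-phase fates, four
groups overall) is testable with any consistent partitioner, and explicit
k removes an unreproducible tuning step. Genes are centered and
unit-scaled (zero-variance genes guarded) before the SVD; k-means uses
k-means++ seeding with Lloyd iterations, keeping the best of `n_init`
seeded restarts by inertia, bit-deterministic given the seed. An optional
top-N-variance gene restriction is off by default since no feature
selection is part of the contract.

### Lineage relatedness

`relatedness_test()` asks whether cells of the same micro-colony have
more similar lag times than the population at large. From the eligible
cells it forms all unordered pairs, splits absolute lag differences into
within-colony and between-colony sets, and offers:

* `pairs_two_sample` (default): one-sided rank-sum test of within <
  between on the two pair-difference sets — the literal two-sample
  comparison;
* `colony_means_one_sample`: one-sided Wilcoxon signed-rank of per-colony
  mean differences against the population mean pairwise difference — the
  dots-versus-reference-line reading of the comparison.

Pair differences sharing a cell are not independent; the result flags
this (`nonindependent_pairs`). The calibration suite quantifies the
consequence under a colony-effect-free null at the study's geometry (133
cells, colonies of 2–4, median 3): the pairs variant's rejection rate at
α = 0.05 stays *below* nominal (shared cells make it conservative, never
anti-conservative), while the colony-means variant — whose observations
are built from disjoint cells — is calibrated, with rejection rate inside
0.05 ± 0.02. Both variants reject at α = 0.001 in ≥ 90% of replicates
when the between-colony standard deviation is twice the within-colony
one. Censoring: by default only cells that resumed growth enter
(`drop_censored` — lag times exist only for resumers); `window_max`
instead assigns non-resumers the observation window as a lower-bound lag.

## The synthetic data generator

`generate_counts()` emulates the data-generating situation of a yeast
droplet run; it is the package's test bed and defines the conditions
under which every downstream guarantee is verified.

Per cell $c$ of population $p$, gene $g$'s expected count is
$\mu_{gc} = \pi_{gp} \cdot \prod_m \lambda_{mc} \cdot L_c$: a population
expression program $\pi$ (relative profile), per-module lognormal latent
activities $\lambda$ (mean 1, sd `latent_sd`) shared by a module's genes
within a cell — the mechanism that plants detectable co-expression — and
a lognormal library factor $L$. Counts are negative-binomial draws
(`dispersion` = NB size, default 1): overdispersion is the observed norm
in droplet data, and a Poisson generator would make every calibration
look better than real data would. Ambient contamination mixes each cell's
expected profile with the library-weighted population-average profile
(the soup released by prematurely lysed cells); doublets add an
independently drawn second transcriptome to a fraction of barcodes; empty
droplets append Poisson-total ambient columns; a damaged fraction of
cells has mitochondrial rates boosted. Each stage consumes its own
derived seed stream, so changing one knob does not scramble unrelated
draws (property-tested).

Default calibrations, chosen once as realistic study conditions:

* library sizes lognormal(log 3000, 0.4) and `empty_umi_mean = 100` —
  filled droplets land in the ~1,000–10,000 total-UMI range with empties
  near 100, the empirically observed separation;
* two 200-gene populations ("glucose"/"maltose") with the maltose marker
  panel induced at a typical gene's expression level and repressed
  2×10⁻⁴-fold under glucose — tight catabolite repression, matching the
  near-binary marker separation a mixed control shows; 60 further genes
  separated 2–4×;
* planted 15-gene modules at `latent_sd = 1.2`, which yields a median
  within-module |r| ≥ 0.3 on normalized values after counting noise (the
  regime the network-recovery guarantee is stated for);
* mitochondrial baseline ~0.1% of the transcriptome (healthy cells sit
  below the 0.2% QC ceiling) with a 20× boost in damaged cells;
* `ambient_fraction = 0.002` and `doublet_rate = 0.02`. The ambient
  default is deliberately below a uniform-soup reading of the
  empty-droplet UMI content (~3% of a filled droplet): the protocol being
  emulated demonstrates minimal premature lysis, and a marker rule at two
  transcripts would visibly misclassify glucose cells at percent-level
  marker contamination — incompatible with the clean separation the
  mixed-control experiment exhibits.

`generate_colony_lags()` draws lag = `lag_mean` + colony effect
(N(0, σ_b²), shared within a colony) + cell noise (N(0, σ_e²)),
truncated at 0; cells censor independently with `nonresume_probability`,
and a drawn lag beyond the observation window (24 h) also censors.
Defaults: 133 cells in colonies of 2–4 (median 3), `lag_mean` 10 h in the
observed 5–20 h+ range, σ_b = 2, σ_e = 1.

`generate_bulk_pair()` builds an fpkm profile proportional to the
pseudobulk totals with mean-one lognormal noise, optionally zeroing genes
on the bulk side to exercise the detection-exclusion bookkeeping.

### What the generator does not emulate

Real droplet data have gene-specific capture biases, zero inflation
beyond NB, barcode errors, sequencing-saturation effects, cell-cycle and
other structured covariates, and transcriptome-wide programs far richer
than a few planted modules. Passing tests therefore demonstrate that the
implementations compute their statistics correctly and recover structure
under the stated generative model — not that any particular biological
dataset will yield publishable modules or clusters. Numbers tied to the
deposited sequencing data (per-sample cell counts, the bulk R² of 0.7,
the 628/374 differentially expressed genes, the published p-values)
require those data and are out of scope; the loading-table arithmetic is
the one externally fixed numeric contract reproduced exactly.

## Numerical choices and degenerate inputs

* Counts are stored dense integer genes × cells; at the package's
  problem sizes (10²–10⁴ cells, ≤ a few thousand genes) dense linear
  algebra is faster and simpler than sparse bookkeeping. MTX I/O emits
  the "coordinate integer" dialect with 1-based indices.
* Correlation values are clamped to [−1, 1] before the t transform;
  |r| = 1 maps to p = 0.
* `pwilcox()` supplies the exact rank-sum null; the enumeration oracle in
  the tests is independent of it.
* k-means++ duplicate seeds are replaced by distinct data points (or
  jittered when fewer than k distinct points exist).
* PCA reduces `n_components` to the data rank with a warning.
* Zero-total cells normalize to zero columns; empty QC inputs, empty
  networks, and colonies without two eligible cells are handled as
  documented rather than erroring where a defined result exists.
* Lineage p-values are floored at the smallest positive double so the
  contract p ∈ (0, 1] holds even when the normal tail underflows.

## Problem sizes used by the verification suite

The suite runs at deliberately desk-scale sizes: DE calibration at 2000
genes × 400 cells; network recovery at 130 genes × 500 cells with two
planted 15-gene modules; clustering at 3 × 150 cells over 200 genes;
lineage calibration over 1000 null and 500 effect replicates of the
133-cell colony design; property suites over dozens of randomized small
matrices. These sizes keep the full suite around a minute while leaving
every statistical check adequately powered.

## Known limitations

* The rank-sum DE test ignores pseudoreplication and count-model
  structure (no negative-binomial GLM); it mirrors the standard
  single-cell practice it re-implements.
* The pairs-based lineage p-value is computed over non-independent pairs
  and is conservative; the colony-means variant is the calibrated choice
  when size matters.
* Gene universes are joined by exact string match; callers must intersect
  universes when reference annotations differ between samples.
* The co-expression Bonferroni family (all post-UMI-filter pairs) is the
  most conservative reading; a narrower family would admit more edges.
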