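---
title: "Methods: transcriptional noise and aging comparisons in snRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptional noise and aging comparisons in snRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txnoise)
```

`txnoise` packages the statistics used to compare young and aged tissue
in a two-group, multi-sample single-nucleus RNA-seq design. This
vignette is the package's own account of what each method assumes, which
parameters matter, and where the design was genuinely open.

## The noise statistic

"Transcriptional noise" here means cell-to-cell dispersion within a cell
type at matched sequencing depth. Raw distances between expression
profiles confound depth with biology: a deeply sequenced cell has more
detected genes and a longer expression vector, so library size must be
removed before cell-to-cell spread is compared between groups.
`transcriptional_noise()` therefore:

1. restricts to one cell type (only types with at least
   `min_cells_noise = 10` young **and** 10 aged cells are analysed —
   below that, a group mean is too unstable to define a distance to);
2. down-samples every cell's UMIs to the minimum library size within
   that type's cells, by an exact multivariate-hypergeometric draw
   (`downsample_umis()`), so every cell has identical depth;
3. down-samples the larger age group, uniformly without replacement, to
   the size of the smaller (`equalize_groups()`), so mean-vector
   stability is matched between groups;
4. computes each cell's Euclidean distance to its own age group's
   cell-type mean (`group_distances()`);
5. reports `log2(mean aged / mean young)` of those distances at the cell
   level and at the sample level (mean of per-sample mean distances per
   group, then the ratio), the latter being robust to a single dominant
   sample.

Choices worth knowing about:

* **Down-sampling target.** The minimum library size *within the
  analysed cell type* (default), not the global minimum: equal depth is
  what makes distances comparable, and it only needs to hold within each
  per-type computation. `target = "global"` switches to the global
  minimum when cross-type comparability of absolute distances matters.
* **Distances on raw down-sampled counts** (default). After depth
  equalization the counts are directly comparable; a `transform =
  "log1p"` flag exists for analysts who prefer variance-stabilised
  distances. Which scale the statistic should use is a genuinely open
  choice; raw is the default because the down-sampling step exists
  precisely to make raw counts comparable.
* **Per-cell seeding.** Each cell's hypergeometric draw is seeded from
  the master seed and the barcode, so results are independent of column
  order and stable when cells are subset.
* A group mean distance of exactly 0 against a nonzero counterpart would
  give an infinite ratio; such types are flagged rather than dropped.

## Differential expression and markers

Aged-vs-young tests within a cell type (`find_degs()`) and one-vs-rest
marker detection (`find_markers()`) use the Wilcoxon rank-sum test on
log-normalized expression (`ln(1 + count/libsize * 1e4)`). The log fold
change is the natural-log, expm1-mean convention,
`ln(mean(expm1(v1)) + 1) - ln(mean(expm1(v2)) + 1)`, so the conventional
cutoffs (0.25 for DEGs, 1.0 for markers) land on their intended scale.
`wilcoxon_test()` returns the exact enumeration p-value whenever the
smaller sample has ≤ 25 observations and the data are tie-free, and the
tie- and continuity-corrected normal approximation otherwise; fully tied
inputs carry no ordering information and return p = 1.

Two conventions that published workflows often leave unstated are
explicit, flagged parameters here:

* **Multiple-testing adjustment** defaults to Benjamini–Hochberg
  (`bh_adjust()`, step-up FDR), chosen for power; `adjust =
  "bonferroni"` reproduces the Seurat default exactly.
* **Detection pre-filter**: genes must be detected in ≥ 10% of cells of
  at least one group (`min_pct = 0.1`, the common default). The filter
  changes the multiple-testing denominator, so it is configurable and
  recorded in the output.

## Module scores and cell-cycle phases

`module_score()` scores a gene set per cell as its mean expression minus
the mean of bin-matched control genes: genes are cut into `nbin = 24`
equal-frequency bins of their dataset-wide average expression and each
set gene draws `nctrl = 100` controls from its bin. Two details are
deliberate:

* Controls are drawn from the **non-set** genes of the bin. This keeps
  the score exactly linear — adding δ to the set genes of a cell moves
  that cell's score by exactly δ — and avoids diluting enrichment when a
  set dominates its bin. (With replacement only when the pool is smaller
  than `nctrl`.)
* The control draw is seeded; in `assign_cell_types()` the seed is
  derived from the panel's gene content, so two cell types given
  identical marker panels receive identical scores and tie exactly into
  the `"ambiguous"` label instead of being separated by sampling noise.

Cell-type annotation is per-cell score-argmax over marker panels (ties
and all-nonpositive scores → `"ambiguous"`), replacing cluster-then-label
workflows: clustering is out of scope here, and argmax annotation is
directly testable against simulated ground truth. Cell-cycle phase uses
the standard rule: S if the S score beats G2M and 0; G2M if it is at
least the S score and positive; else G1.

## Ligand–receptor testing

`permutation_test()` scores a pair for a (sender, receiver) type
combination as the average of the ligand's sender-type mean and the
receptor's receiver-type mean of normalized expression, with
multi-subunit complexes represented by their minimum-mean subunit (a
complex is only as available as its scarcest subunit, and only as
detected as its least-detected one in the >10% gate). The null
distribution shuffles cell-type labels within the age group, preserving
type sizes; `p = (1 + #{perm ≥ obs}) / (n_perm + 1)` — the add-one rule
keeps p positive and conservative. Groups are tested separately over a
shared pair universe and classified by `compare_groups()` into
young-only (lost with age), aged-only (gained), or shared. Whether the
gate's ">10% in any type of either group" should instead be enforced per
side and per group is ambiguous; the literal any-type/either-group
reading is the default.

## The simulator

`simulate_counts()` draws gene × cell UMI matrices from a negative
binomial: `mu = profile[gene, type] × libfactor`, `size =
nb_dispersion`, with per-cell lognormal library factors (so the
down-sampling step of the noise metric is non-trivially exercised). The
count distribution is an assumption of this generator, not an observed
property of any particular dataset; NB is the standard overdispersed
choice for UMI counts. Planted effects map one-to-one onto the
statistics under test:

* **DEGs**: the mean is multiplied by `exp(delta)` in aged cells of the
  stated type;
* **noise**: the NB size is divided by φ ≥ 1 in aged cells of inflated
  types — dispersion grows at fixed mean, which is exactly what the
  distance statistic should detect at matched depth;
* **markers**: panel genes are upregulated by `exp(1.5)` in their type;
  default panels have 8 genes, a size at which module-score annotation
  is stable;
* **ligand–receptor activity**: ligand (in sender) and receptor (in
  receiver) are upregulated by `exp(2)` only in the groups where the
  pair is active.

The default design is four young and four aged samples — the
two-group multi-sample layout this package targets — with a catalogue of germ and
somatic testis cell types. Each sample has its own named RNG substream
derived from the master seed, so adding a sample leaves the others'
cells bit-identical. Recovery and calibration checks in the test suite
run at 1,000 genes and ~300 cells per type per age group (six types),
sizes at which every planted effect is comfortably detectable and a
20-seed replicate completes in minutes; the worked examples use smaller
instances. What the simulator does **not** emulate: ambient RNA,
doublets, batch effects, gene–gene correlation, or realistic gene-length
and GC structure — passing recovery tests shows the statistics behave
correctly under their own assumptions, not that any particular biological
dataset satisfies those assumptions.

## Numerical and degenerate-input conventions

* QC keeps cells with `n_genes ≥ 200` and `mito_fraction ≤ 0.05` — the
  strictness follows the filter's usual phrasing ("below 200" and
  "greater than 5%" are discarded). The mitochondrial fraction is the
  UMI fraction (not gene-count fraction) of genes matching a
  configurable name prefix (`"MT-"` by default; annotation conventions
  differ across genomes). Zero-library cells get `mito_fraction = 0` and
  a flag.
* MatrixMarket output is written as `coordinate integer` with genes as
  rows and 1-based indices, so integer matrices round-trip bit-exactly.
* Equal-frequency binning breaks ties by original gene order
  (`ties.method = "first"`), making module scores fully deterministic
  given the seed.
* BH adjustment and the Wilcoxon machinery call the base R
  implementations (`p.adjust`, `wilcox.test`); the test suite checks
  them against independently coded closed forms and exhaustive
  enumeration rather than re-implementing them in the package.
* `filter_cells()` is idempotent; empty filter results are allowed with
  a warning, since downstream stages validate their own inputs.

## Known limitations

* The noise statistic compares dispersion around a *single* group mean;
  a cell type with young/aged sub-states would register the sub-state
  shift as noise. That is a property of the distance definition, not an
  implementation choice.
* Per-cell argmax annotation does not borrow strength across similar
  cells the way graph clustering does; with weak marker panels the
  `"ambiguous"` fraction grows (counts are logged for exactly this
  reason).
* Permutation p-values are bounded below by `1/(n_perm + 1)`; at the
  default 1,000 permutations the 0.01 cutoff is near the resolution
  limit, and results within binomial noise of the boundary should be
  read accordingly (`compare_groups()` reports raw p-values so this is
  visible).
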