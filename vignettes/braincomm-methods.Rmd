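---
title: "Integrated ligand-receptor communication scoring and perturbation subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated ligand-receptor communication scoring and perturbation subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincomm)
```

## The problem

Brain cell types — astrocytes, endothelial cells, microglia, neurons,
oligodendrocyte progenitors (OPC) and oligodendrocytes — communicate through
ligand-receptor signaling, and this communication is remodeled by disease,
sex and brain region. Single published communication scorers disagree
substantially on which ligand-receptor interactions are active, so
`braincomm` integrates four scoring schemes into one **ISIscore** per
(ligand-receptor pair, sender type, receiver type) and builds three analyses
on top of it: condition-specific communication calling, rank-based
subtyping of disease samples from bulk transcriptomes, and a
communication-gene disease classifier.

## The scoring model

Expression is summarized per annotated cell type from a log-normalized
matrix (`normalize_log()`, target total 10,000 per cell). For a pair with
ligand summary $l$ in the sender and receptor summary $r$ in the receiver
(multi-subunit complexes such as `BMPR1A+ACVR2A` are aggregated by the
geometric mean, so a silent subunit abolishes the complex), the four
scorers are

* **hill** — $\dfrac{l\,r}{0.5 + l\,r}$ on Tukey trimeans
  ($\tfrac{Q_1 + 2Q_2 + Q_3}{4}$, linear-interpolation quartiles): a
  saturating mass-action score, robust to expression outliers;
* **regularized** — $\dfrac{\sqrt{l\,r}}{\mu + \sqrt{l\,r}}$ on means,
  with $\mu$ the global mean of the normalized matrix as regularizer;
* **product** — the product of per-gene means min-max scaled to $[0, 10]$
  across cell types (so the score reflects *relative* specificity, range
  $[0, 100]$; a constant nonzero gene scales to 10, a silent one to 0);
* **gated** — the product of means, emitted only when each gene passes a
  gate in its type: detection fraction $\ge 0.10$ and mean above the
  gene's across-type mean. Failing the gate yields an *absent* entry, not
  a zero — absence is what triggers zero-imputation at integration.

Within one sub-dataset each method's present scores are min-max normalized
to $[0, 1]$; absent entries impute 0; the ISIscore is the arithmetic mean
of the four components. Min-max is used deliberately: a z-score does not
produce the $[0, 1]$ range the integration requires. Degenerate method
tables (all present scores equal) map to 1 if positive, 0 otherwise.
Triples with ISIscore zero in every sub-dataset are pruned before testing.

## Condition-specific communication

Two groups of sub-datasets (e.g. disease vs normal) are compared per
(pair, sender, receiver) key with a two-sided Wilcoxon rank-sum test, and
a key is condition-specific when $p < 0.05$ *and*
$|\log_2((\bar{s}_A + \varepsilon)/(\bar{s}_B + \varepsilon))| > 3$
(strict inequalities, pseudocount $\varepsilon = 10^{-3}$ so zero means
are tolerated). Base 2 and the strict cutoff of 3 make "specific" an
eight-fold mean contrast. A Benjamini-Hochberg column is emitted for
reference but does not drive calls, matching the raw-p convention of the
analyses this package reproduces.

The Wilcoxon sampling unit is the per-sub-dataset ISIscore whenever both
groups contain at least three sub-datasets. A rank-sum test cannot run on
one score per group, so with fewer sub-datasets the samples fall back to a
per-cell unit: for each sender cell, its (complex-aggregated) ligand value
times the receiver-type mean receptor value within the same group. One
sample per sender cell keeps the test size bounded, and shifts on either
the ligand or the receptor side move the cross-group ranks. The output
records which unit was used.

The p-value policy: exact for groups of up to 25 without ties; with ties,
`wilcox.test()` abandons exactness, so small tied problems (at most
20,000 group assignments) are solved by exact permutation of the average
ranks; everything larger uses the normal approximation with continuity
correction.

## Edge-perturbation subtyping

Bulk expression is reduced to within-sample gene ranks (average ranks for
ties) over the genes of the specific pairs; each edge becomes
rank(ligand) − rank(receptor); the reference is the same quantity on the
single ranking of mean normal expression; the perturbation matrix is the
disease edge matrix minus the reference vector. Because a disease sample
enters only through its own ranks, the matrix is invariant to any strictly
increasing per-sample transform of the disease samples. The reference is
deliberately the paper-style mean-expression ranking, so transforms that
reorder the normal means would move it; the invariance is therefore stated
and tested over the disease side.

Subtypes come from subsampled consensus clustering: per repetition, 80% of
samples and 80% of edges are drawn without replacement and PAM (k-medoids,
Euclidean distance) partitions the subsample for each $K \in \{2..6\}$.
The consensus entry for a sample pair is its co-cluster count over its
co-sample count. $A(K)$ is the area under the empirical CDF of
off-diagonal consensus values; the relative delta area is
$\Delta(2) = A(2)$ and $\Delta(K) = (A(K) - A(K-1))/A(K-1)$, and the
chosen $K$ is the largest one with $\Delta(K)$ above a configurable floor
(default 0.1) — an explicit operationalization of "the area change slows
down", which is otherwise a visual call. Final labels are PAM on
$1 - \text{consensus}$ at the chosen $K$.

PAM here is BUILD + SWAP with five random restarts (`pam_kmedoids()`).
Single-start BUILD + SWAP is a local search over one-medoid swaps and
demonstrably misses the global optimum on a few percent of even tiny
instances; with restarts the tests verify it matches the exhaustive
medoid-pair optimum on every random instance tried. Per-repetition seeds
are derived from the master seed by repetition index, so results are
reproducible and independent of repetition order.

## Disease prediction

The genes of the condition-specific pairs (subunits flattened,
deduplicated) feed a gradient-boosted tree classifier (200 trees, depth 3,
learning rate 0.1 — fixed, unremarkable defaults; no tuning) on a bulk
cohort with a stratified 75/25 split. The split is stratified rather than
simply random to avoid degenerate test sets at small cohort sizes. AUC is
computed by the rank (Mann-Whitney) formulation, which the tests check
against independent ROC integration.

## What the synthetic generator emulates

`simulate_sc()` draws negative-binomial counts,
$\text{Var} = \mu + \mu^2/\theta$, with $\theta = 2$ by default — a
squared biological coefficient of variation of 0.5, typical of UMI data.
Per-gene baselines are log-normal around `nb_mean` (sdlog 1), giving the
right-skewed mean distribution real data shows. Structure on top of the
baseline:

* each of the six types elevates its five canonical markers (GFAP, CLDN5,
  CX3CR1, SLC17A7, PDGFRA, MAG, ...) **and** a disjoint block of 25
  "program" genes by `marker_fold` (default 4). Five markers alone do not
  make noisy cells separable; real types differ by whole transcriptional
  programs, and the program block is what lets graph clustering recover
  them;
* ligand/receptor genes get a *home-type* structured baseline: mean
  `nb_mean/4` off-home and 8-fold that in a deterministically assigned
  home type (never a type carrying a planted signal). Real ligands and
  receptors are expressed in specific types; without this structure every
  moderately expressed pair scores mid-range after min-max normalization
  and no contrast can reach the eight-fold specificity cutoff;
* planted communication: under a matching condition label, the ligand is
  multiplied by `signal_fold` in sender cells and the receptor in
  receiver cells — elevation only under the pair's condition;
* mitochondrial content: a configurable fraction of cells has mito means
  inflated to an expected 35% share (5% otherwise), exercising the
  strict >20% QC filter.

Gene baselines depend only on the config seed; sampling noise also on the
sample id, so sub-datasets share structure but not noise, exactly like
replicate datasets of one tissue.

`simulate_bulk()` plants subtypes as additive log2-scale shifts: each
subtype lowers its own edge ligands and raises its receptors by
`rank_shift`, directly manipulating the rank statistic the subtyping
consumes; normal samples share the baseline plus Gaussian noise.

The generator does **not** emulate batch effects, doublets, ambient RNA,
cell-size covariates or spatial structure. Passing tests therefore show
the machinery is correct under its stated noise model, not that the
pipeline is robust to those artifacts in real data.

## Numerical and design choices

* Mito genes are flagged by symbol prefix (`MT-`/`mt-`); the threshold is
  strictly greater than 20%, so a cell at exactly 0.20 survives.
* Fixed `n_pcs = 20` and Louvain resolution 0.8 replace visual
  elbow-plot / cluster-tree choices, which are not reproducible
  programmatically; both are exposed as arguments.
* HVG selection standardizes counts by a loess mean-variance trend
  (span 0.3), clips at $\sqrt{n_\text{cells}}$, and breaks ties
  lexicographically by gene id for determinism.
* Cluster annotation tests only genes present in the marker database:
  genes outside it cannot contribute to the overlap count that drives
  assignment, so the restriction is exact and much faster. Assignment
  ties go to the larger mean log fold-change over overlapping markers;
  zero overlap everywhere yields `"other cells"`.
* Genes referenced by a pair but absent from a matrix are treated as
  zero-expressed (score 0, or a gated absence), not as an error.
* Sub-datasets below 50 cells are dropped at partitioning; profiles
  exclude types with fewer than 3 cells.

## Problem sizes

The shipped tests and the acceptance script run, per scenario, six brain
types at 60 cells each (~360 cells, 330-360 genes), 10 + 10 sub-datasets
for null calibration, 5 + 5 for planted-signal recovery, an 80-sample
disease cohort with 4 planted subtypes at 250 consensus repetitions, and
an 80-sample prediction cohort — sizes chosen so the full suite exercises
every stage end to end in about a minute on one core. The consensus
default of 1000 repetitions is used for real analyses; 250 already yields
stable consensus matrices at these cohort sizes.

## Known limitations

* The four scorers are representative formulas for the four families of
  published methods, not re-implementations of the original tools; raw
  scores are not comparable to any of them, only the integration behavior
  is.
* Min-max normalization couples all keys of one sub-dataset: the
  *fraction* of null keys below any p cutoff fluctuates more than
  independent-key binomial sampling would suggest, although each key's
  test remains individually valid.
* With a single sub-dataset per condition the per-cell fallback treats
  cells as independent samples, which understates between-dataset
  variability; calls made on that path deserve more caution, and the
  output flags them.
* K selection inherits the arbitrariness of any delta-area rule; the
  floor (0.1) is a declared default, not an estimate.
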