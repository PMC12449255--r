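---
title: "Co-embedding peaks and genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-embedding peaks and genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Paired single-cell multiome experiments measure chromatin accessibility
(scATAC-seq peaks) and gene expression (scRNA-seq) in the same cells. The
question scpoem addresses is which open-chromatin peaks regulate which
genes in *cis*. Direct per-gene regressions of expression on nearby peak
accessibility are noisy because both modalities are sparse; scpoem instead
pools three sources of association — peak–peak co-accessibility, gene–gene
co-expression, and peak–gene regression — into one heterogeneous network,
and learns a single low-dimensional space in which a peak and a gene lie
close together when many direct *and higher-order* paths connect them.

The pipeline has four stages.

**1. Preprocessing.** Cells outside configurable total-count ranges
(defaults: 1st–99th percentile of per-cell totals) or above a 20%
mitochondrial read fraction are removed. Features on X, Y, mitochondrial
or nonstandard chromosomes are dropped, as are peaks detected in fewer
than 5 cells and genes detected in under 1% of cells. RNA counts are
library-size normalized to a common target, log1p-transformed, reduced to
the 3000 most variable genes (trend-standardized dispersion), and z-scaled
per gene. ATAC counts are TF-IDF weighted: term frequency is the count
over the cell total, inverse document frequency is
`log(1 + n / (1 + n_detected))`.

**2. The joint network.**

* `Wpp` (peak–peak): the standard co-accessibility workflow — binarize,
  embed cells, sum each cell's `knn_k = 50` nearest neighbors into a
  metacell profile, then fit an L1-penalized inverse covariance
  (graphical lasso) inside overlapping 500 kb genomic windows and average
  the absolute partial correlations of each pair over the windows that
  contain it. Cross-chromosome entries are structurally zero.
* `Wgg` (gene–gene): for each gene *j*, regress its normalized expression
  on the leading `K = 5` principal components of the remaining genes and
  map the coefficients back to genes (`beta = V alpha`). Absolute values
  are symmetrized by elementwise maximum and only entries above the 95th
  percentile of the off-diagonal values are retained.
* `Wpg` (peak–gene): per gene, regress expression on the TF-IDF profiles
  of the peaks overlapping the gene body ± 100 kb, under three regressors
  — lasso (absolute coefficients), random forest (impurity importance)
  and XGBoost (gain importance).

**3. Meta-path walks.** Each weight matrix is winsorized at the 10th and
90th percentiles of its nonzero values and row-normalized into transition
matrices `Ppp`, `Pgg`; the three peak–gene matrices (and their
transposes) are row-normalized and averaged into `Ppg` and `Pgp`. Walks
follow the fixed typed scheme P3–P2–P1–G1–G2–G3: every peak and every
gene roots one walk per loop, and each realized walk contributes five
node pairs per root, weighted `exp(-0.1 k)` where `k` counts the
intermediate nodes separating the pair (so direct neighbors weigh 1,
second order `exp(-0.1)`, third order `exp(-0.2)`).

**4. Embedding.** A skip-gram model with negative sampling maximizes
`sum_r w_r (log sigma(F_v . F_u) + sum_m log sigma(-F_c . F_u))` over the
pair multiset, with `M = 5` negatives drawn uniformly over all nodes per
pair, one shared embedding table for both roles, minibatch (32) gradient
ascent. Peak–gene candidates are then ranked by Euclidean distance
`d_uv = ||F_u - F_v||`, reported alongside the importance score
`exp(-d_uv)`.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `window_bp` (peak–gene) | 100 000 bp | cis candidate window around the gene body |
| `coaccess window_bp` | 500 000 bp | genomic window of the graphical-lasso fits |
| `glasso_penalty` | 0.2 | sparsity of partial-correlation edges; chosen so planted co-accessibility blocks are recovered cleanly (smaller values let factor-structured blocks wash out after conditioning) |
| `knn_k` | 50 | smoothing of the metacell aggregation |
| clip quantiles | 0.10 / 0.90 | winsorization of nonzero edge weights before row normalization |
| `Wgg` percentile | 0.95 | edge retention threshold, computed over all off-diagonal entries (zeros included; configurable to nonzero-only) |
| `d` | 100 | embedding dimensionality (the validation suite uses 32 at its reduced problem size) |
| `batch_size`, `learning_rate` | 32, 0.1 | SGD settings; the rate decays linearly to 0.001 by default |
| `max_epochs` | 100 | epoch budget (50 in the validation suite) |
| `M` | 5 | negatives per pair, uniform over all nodes |
| `paths_per_node` (`T`) | 5 | walks rooted at each node per epoch |

## Design choices where the design was open

* **Cell embedding for co-accessibility.** The workflow this stage
  follows typically reduces cells with UMAP before neighbor aggregation.
  The default here is a deterministic truncated SVD of the TF-IDF-scaled
  binary matrix: the neighbor graph it induces serves the same purpose,
  and exact reproducibility under a fixed seed is part of this package's
  contract. UMAP remains available (`embed_method = "umap"`).
* **Regressor regularization.** After quantile clipping, edge *existence*
  carries most of the transition signal, so the peak–gene regressors are
  configured to zero out uninformative peaks: the lasso penalty is chosen
  by 5-fold cross-validation at the parsimonious `lambda.1se`, and random
  forests use debiased (`impurity_corrected`) importances clamped at
  zero. Plain `lambda.min` or raw impurity importances are available
  through `hyper`.
* **Walk resampling.** Five walks per node are resampled every training
  epoch (seeded), so the pair stream converges to the expected transition
  statistics; a single static pair multiset is available with
  `resample_paths = FALSE`.
* **Learning-rate schedule.** The stated rate (0.1) is treated as the
  initial rate of a linear decay to 0.001, the word2vec-family
  convention; a constant schedule is available. With a constant rate the
  final SGD iterate is visibly noisier and distance rankings degrade.
* **Early stopping.** The default trains the full epoch budget; an
  optional plateau rule (improvement < 1e-4 for 5 consecutive epochs on
  the fixed-negative evaluation objective) can be enabled.
* **Dead ends.** A node whose transition row is all zero cannot emit the
  affected branch; walks truncate there and only realized pairs are
  emitted. Restarting cannot help, because dead rows are structural.
* **Ensemble rows.** A peak–gene transition row dead in some but not all
  methods is renormalized so every live row sums to one; a row dead in
  all three stays dead.
* **Symmetrization and thresholds.** `Wgg` is symmetrized by elementwise
  maximum (keeping the stronger directed estimate); the 95th percentile
  is computed over all off-diagonal entries including zeros. Both are
  configurable.
* **Window anchor.** Cis windows span the gene body ± `window_bp`; a
  TSS-anchored mode is available.
* **Differential regulation.** The two conditions' gene embeddings are
  turned into cosine-similarity KNN graphs (k = 20, negative similarities
  clamped at zero) and jointly embedded by a joint-Laplacian manifold
  alignment with same-gene anchor edges. The anchor weight defaults to
  the maximum graph degree: antisymmetric eigenvectors then pay at least
  twice that weight, so the leading aligned dimensions are
  anchor-consistent and identical inputs give displacements at numerical
  zero. Significance, when requested, comes from permuting the gene
  correspondence; note this null is conservative because any
  misalignment inflates all displacements.
* **Gene subgrouping.** Size-constrained clustering is k-means followed
  by a greedy repair pass (moving members out of oversized clusters into
  the nearest cluster with capacity, pulling nearest members into
  undersized ones), which guarantees the size window exactly.

## The synthetic data generator

`simulate_multiome()` emulates the data-generating assumptions the method
relies on: contiguous peak blocks share one latent per-cell factor each
(co-accessibility is block-diagonal), genes belong to co-expression
modules driven by separate factors, and each linked gene's log-mean
expression follows the latent accessibility of its planted peaks —
including the peak-specific component, which is what makes a planted
peak identifiable among its block mates. ATAC counts are thinned
binomials of latent open states; RNA counts are negative binomial with
configurable dispersion; both modalities have dropout thinning. Planted
links always lie inside the ± 100 kb window and share it with decoy
peaks.

The defaults (500 cells, 200 peaks on two 1 Mb chromosomes, 40 genes of
which 20 carry one planted link, effect size 3 on the log scale, 10%
dropout) are the benchmark condition used throughout the package's own
validation. What the generator does **not** emulate: fragment-level ATAC
structure, batch effects, multiple cell types, doublets, and realistic
gene density. Passing tests therefore demonstrate that the machinery
recovers planted structure under the stated noise model — not
performance on real tissue.

## Numerical choices

* Quantiles use R's default linear interpolation (type 7) everywhere.
* The graphical lasso penalizes off-diagonal entries only; singular
  window covariances are ridge-stabilized (`1e-4` of the mean diagonal)
  and logged. With zero penalty the estimate equals the matrix inverse.
* Log-sigmoid is evaluated in the numerically stable branch form.
* Nearest-peak ties break by peak order, making rankings deterministic.
* All randomness flows from user seeds through R's RNG, including the
  C++ SGD inner loop, so equal seeds give byte-identical embeddings.
* Constant genes z-scale to zero columns; cells emptied by feature
  filtering are dropped before normalization.

## Validation problem sizes

The test suite exercises the full pipeline at 500 cells x 200 peaks x 40
genes with a 32-dimensional embedding, 5 walks per node and 50 epochs —
five replicate seeds for planted-link recovery (median window-pair AUROC
above 0.8, planted pairs closer than decoys in every seed), two 90% cell
subsamples for rank stability against a label-shuffled control, and a
rerun for byte-level reproducibility. Smaller fixtures (150 cells, 60
peaks, 12 genes) back the per-stage tests.

## Known limitations

* The walk scheme is fixed at length six (three peaks, three genes);
  longer meta-paths are out of scope.
* Every gene roots a walk each loop, so a gene with no real regulatory
  signal still bonds to its least-implausible peak; rankings for such
  genes are noise.
* The quantile clip deliberately flattens edge magnitudes; at small
  problem sizes this makes support sparsity (which peaks survive the
  regressors) the dominant signal.
* Dense distance computation and the exact KNN search are quadratic in
  nodes and cells respectively; the package targets single-cell-type
  desk-scale analyses.
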