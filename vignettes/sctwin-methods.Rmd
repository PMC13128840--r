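---
title: "sctwin: model, design choices and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sctwin: model, design choices and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The integration model

`sctwin` integrates `D` batches of single-cell expression profiles by
self-supervised representation learning without negative samples. The
working assumption is that a cell's identity is stable under small random
corruptions of its measured expression vector, while batch membership is a
nuisance variable whose first- and second-order statistics can be absorbed
by normalization layers. Two distorted views of every mini-batch are
embedded by one shared encoder–projector; the objective asks that (i) each
embedding dimension agree across the two views (invariance) and (ii)
different embedding dimensions be uncorrelated (decorrelation), evaluated
separately within every batch.

Concretely, per domain `d` the projector outputs of the two views are
z-scored along the batch axis with population variance over the
per-domain mini-batch of size `K`, so the cross-correlation matrix is a
single matrix product `W(d) = (1/K) Y'(d)ᵀ Y''(d)`, and

```
L(d) = sum_i (1 - W_ii)^2  +  lambda * sum_{i != j} W_ij^2,
L    = mean over domains of L(d).
```

Because all domains share the encoder weights and are optimized toward
the same targets (unit diagonal, zero off-diagonal after per-domain
standardization), cells with similar programs land near each other
regardless of batch — alignment is implicit, with no cross-batch matching
loss.

## Architecture

The encoder is a densely connected MLP: `encoder_depth - 1` fully
connected layers of width `encoder_growth`, each consuming the
concatenation of the raw input and all previous layers' outputs, each
followed by domain-specific batch normalization (DSBN) and ReLU; a final
linear layer over the full concatenation yields the 64-dimensional
representation `Z`. `encoder_depth` counts linear layers, so the stock
profiles are depth 11 with a 512-512-512 projector ("S", mini-batch
K = 512, for datasets under 50k cells) and depth 21 with a 1024-1024-1024
projector ("L", K = 2048). The boundary is resolved as "S strictly below
50k cells". The growth width (default 64) is this package's choice; dense
connectivity fixes only the wiring, not the width.

The projector is three linear layers; the first two are each followed by
ReLU and DSBN, the third is bare. The z-scoring in the loss is itself a
DSBN layer with no affine parameters, implemented as plain per-domain
standardization of the current mini-batch (no running statistics) since
it only exists during training.

DSBN keeps separate running means/variances and separate affine
parameters per domain everywhere a normalization layer occurs — including
the encoder. Making *all* normalization domain-specific is the consistent
reading of the domain-adaptation strategy; the statistics of domain `d`
are never touched by cells of another domain.

All forward and backward passes are written directly in R matrix algebra
(BLAS-backed); gradients are analytic and verified against central finite
differences in the test suite. Two parameters — biases feeding directly
into a normalization layer, and the third projector bias, which the loss
z-scoring removes — provably receive zero gradient; they are kept for
architectural fidelity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lam` | 0.005 | invariance/decorrelation trade-off; the canonical value of the feature-decorrelation objective this builds on. The off-diagonal sum is not additionally scaled by 1/P. |
| `mask_fraction` | 0.2 | fraction of genes zeroed per cell per view |
| `shuffle_fraction` | 0.1 | fraction of expression values permuted within a cell |
| `p_apply` | 0.5 | per-transform, per-view, per-mini-batch firing probability |
| `K` | 512 (S) / 2048 (L) | per-domain mini-batch size |
| `base_lr` | 3e-4 | Adam peak rate; 10-epoch linear warmup then cosine annealing to 0 |
| `epochs` / `patience` | 1000 / 50 | maximum epochs; early-stopping patience on validation loss |
| `val_fraction` | 0.1 | per-domain held-out fraction for the validation loss |

Augmentation interpretation: "applied with probability 0.5" is read per
transform, per view, per mini-batch (not per cell), with mask before
shuffle when both fire; the masked/shuffled index sets are drawn
independently per cell. Shuffling permutes values *within* a cell — the
reading that keeps each view a plausible profile of the same cell.

## Training loop

Each epoch runs `ceil(max_d n_d / K)` steps; every step draws `K` cells
from every domain (without replacement within a shuffled per-domain
cycle; domains smaller than `K` are resampled with replacement), builds
the two views, accumulates the domain-averaged gradient and takes one
Adam step (β = 0.9/0.999, no weight decay). The validation loss uses the
same augmented objective under a fixed augmentation seed so successive
epochs are comparable, with batch statistics computed on the validation
batch but no running-statistics update. The checkpoint with the best
validation loss is returned. One global seed drives initialization
(Kaiming-uniform linear weights), sampling and augmentation; runs are
bit-reproducible on a single thread.

Numerical guards: population (1/K) variance in the loss z-scoring with
1e-8 added to the standard deviation (constant columns map to zeros);
DSBN uses variance epsilon 1e-5 and running-statistics momentum 0.1;
non-finite losses abort with the epoch and step.

## Evaluation protocol

**Integration.** Leiden clustering (modularity objective) of the k = 15
Euclidean kNN graph is swept over resolutions 0.1–1.0 (step 0.1); the
reported ARI and NMI come from the single resolution maximizing
(ARI + NMI)/2 — the joint reading of "best average ARI and NMI" — with
ties to the smaller resolution. ARI uses the closed-form pair-counting
formula, NMI arithmetic-mean normalization. Cell-type silhouette is
rescaled `(s+1)/2`; batch silhouette scores each cell type present in ≥ 2
batches by `mean(1 - |s|)` under batch labels. Graph connectivity is the
mean largest-connected-component fraction of each type's induced kNN
subgraph. Batch entropy samples 100 anchors × 10 repeats, takes k = 30
neighbours among cells of shared types, reweights batch counts by inverse
global frequency and normalizes Shannon entropy by `log(#batches)`;
overcorrection is the mean same-type fraction among k = 30 neighbours
(1 = no mixing of distinct types). These free parameters are fixed here
because the protocol defers to external implementations that do not pin
them. Aggregation min-max normalizes each metric across the supplied runs
(a degenerate range maps to 0.5 — symmetric and division-free), then
`S_integration = 0.6·S_bio + 0.3·S_batch + 0.1·S_oc`. Silhouette widths
of singleton clusters, and of degenerate all-equal configurations, are 0.

**Label transfer.** Each query batch is held out in turn; k for the kNN
classifier is chosen by 3-fold class-stratified cross-validation on the
reference over the 33-value grid 5, 11, …, 197, maximizing balanced
accuracy with ties to the smaller k (classes with fewer than 3 members
are dropped from CV folds but kept for the final fit). Classification is
restricted to cell types shared between reference and query; votes are
uniform over Euclidean neighbours, with deterministic tie-breaking toward
the class of the nearest tied neighbour. Query clustering quality reuses
the Leiden sweep on the full embedding with the best resolution selected
by the query-restricted score; the query cell-type silhouette is computed
on the query cells' own embedding (not full-embedding distances), the
stricter and more local reading. Per-batch scores are min-max normalized
across runs within the batch, combined with equal weights into
`S_label_transfer`, and averaged over batches.

kNN search is exact (blocked Euclidean distances): deterministic, and
entirely adequate at the problem sizes this package targets; an
approximate index would only matter beyond ~10⁵ cells.

## Preprocessing

Genes expressed in fewer than 3 cells are removed; each cell is scaled to
a total of 1e4 and natural-log(1+x) transformed; the top 2000 highly
variable genes are selected per batch by the clipped-standardized-variance
("vst") criterion computed on raw counts — the canonical input for that
criterion — with a loess mean–variance trend (span 0.3, log10 scale,
linear-fit fallback for tiny inputs) and clipping at sqrt(n). Batches are
combined by (number of batches in which the gene is in that batch's top
set, descending; median within-batch rank ascending). Cells with zero
total counts are kept as all-zero rows: no cell filtering is part of the
protocol, and silently dropping cells would surprise downstream joins.

## The count simulator

`simulate_counts()` emulates the structure the integration task cares
about: per-type expression programs (a `de_gene_frac` subset of genes per
type multiplied by `exp(N(0, de_logfc_scale²))` fold changes over
gamma-distributed baseline means, shape 0.6 / rate 0.3), per-batch
gene-wise technical factors `LogNormal(0, batch_effect_scale²)`, per-cell
library factors `LogNormal(libsize_logmean, libsize_logsd²)`, and
negative-binomial sampling with variance `mu + mu²/r`. Batch-specific and
rare cell types fall out of zero or small entries in the per-domain
proportion rows.

The defaults define the reference study conditions used throughout the
tests: 3 domains × 1000 cells, 500 genes, 5 shared types in equal
proportion, `de_gene_frac = 0.1`, `de_logfc_scale = 1` (clear but
overlapping programs), `batch_effect_scale = 0.3` — a moderate effect:
strong enough that unintegrated PCA mixes batches poorly, well below the
≥ 1 regime where batches separate outright — `libsize_logsd = 0.3` and
dispersion `r = 2`, all typical of negative-binomial scRNA-seq
simulators. At these sizes the reduced evaluation network (depth 5,
growth 32, projector 128-128-128, K = 256, up to 200 epochs) trains in a
few minutes on one CPU; these problem sizes are the package's chosen
reference scale.

What the simulator deliberately lacks — gene–gene correlation beyond
type membership, doublets, ambient RNA, spliced/unspliced structure,
nonlinear batch distortions — bounds what passing tests demonstrate:
recovery of type structure under multiplicative batch effects and NB
noise, not performance on the full messiness of real atlases.

## Known limitations

* Inference is only defined for domains seen during training: DSBN has no
  statistics for an unseen batch, and `embed_cells()` refuses it.
  Integrating a new batch requires retraining or fine-tuning.
* Training is single-threaded CPU matrix algebra; practical up to tens of
  thousands of cells, not millions.
* The h5ad interchange format is not read or written; datasets move as
  MTX + TSV triplets (plus serialized R objects for checkpoints with a
  JSON sidecar describing the configuration).
* Min-max aggregate scores are only meaningful relative to the set of
  runs supplied; a single run degenerates to 0.5 by construction.
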