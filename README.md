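# sctwin

Self-supervised integration of multi-batch single-cell RNA-seq data by
twin-view feature decorrelation with domain-specific batch normalization,
plus the full downstream evaluation protocol (data-integration scoring and
reference-to-query label transfer).

## The problem

Cells profiled in different batches (donors, studies, chemistries) carry
systematic technical variation that confounds biological signal. Most
integration methods align batches with explicit matching machinery —
anchors, adversaries, or negative pairs. `sctwin` instead learns a shared
representation with no negative samples at all: it only asks that the
embedding of a cell be invariant to random distortions of its expression
profile and that embedding dimensions be mutually decorrelated, with all
normalization statistics kept separate per batch. Alignment across batches
emerges implicitly because every batch is optimized toward the same
normalization and decorrelation targets through one shared encoder.

## The model

Two stochastic views of each mini-batch (random zeroing of 20% of genes,
random within-cell shuffling of 10% of expression values, each applied
with probability 0.5) pass through a Siamese encoder–projector with shared
weights. The encoder is a densely connected MLP producing 64-dimensional
representations *Z*; the projector maps them to embeddings *Y*. Every
normalization layer is **domain-specific batch normalization (DSBN)**:
separate running statistics and affine parameters per batch *d*, all other
weights shared.

For each domain the projector outputs of the two views are z-scored along
the batch axis (population variance over the per-domain mini-batch of size
*K*), giving the cross-correlation matrix by a plain matrix product:

    W(d) = (1/K) Y'(d)ᵀ Y''(d)

with the per-domain loss

    L(d) = Σᵢ (1 − Wᵢᵢ)² + λ Σᵢ Σ_{j≠i} Wᵢⱼ²

(invariance term pushes matching dimensions of the two views to perfect
correlation; decorrelation term suppresses redundancy; λ = 0.005 by
default), and the training objective is the mean over domains
`L_DA = (1/D) Σ_d L(d)`. Optimization: Adam at base rate 3e-4, 10-epoch
warmup then cosine annealing, early stopping on a held-out per-domain
validation split (patience 50). The network and its analytic backward pass
are implemented directly in R matrix algebra.

Downstream, the package scores integration with a Leiden resolution sweep
(ARI/NMI), cell-type and batch silhouettes, graph connectivity, batch
mixing entropy and an overcorrection index, aggregated by min-max
normalization into `S_integration = 0.6·S_bio + 0.3·S_batch + 0.1·S_oc`;
and label transfer by leave-one-batch-out kNN classification (3-fold
cross-validated k over 5, 11, …, 197) with batchwise clustering scores,
aggregated as `S_label_transfer = 0.5·S_classify + 0.5·S_bw_bio`.

A seeded negative-binomial simulator (`simulate_counts()`) generates
multi-batch data with known cell-type programs, per-batch gene-wise
effects and library-size variation for all tests and examples.

## Worked example

```r
library(sctwin)

sce  <- simulate_counts(sim_config(seed = 1))   # 3 batches x 1000 cells
prep <- preprocess(sce)                          # filter, log-normalize, HVG

ncfg <- net_config(input_dim = nrow(prep), n_domains = 3,
                   encoder_depth = 5, encoder_growth = 32,
                   projector_dims = c(128, 128, 128))
ckpt <- fit_sctwin(prep, ncfg, train_config(K = 256, epochs = 200, seed = 1))
Z    <- embed_cells(prep, ckpt)                  # cells x 64

cd <- SummarizedExperiment::colData(prep)
leiden_sweep(Z, cd$cell_type, seed = 1)$ari
#> [1] 0.8436055
batch_entropy(Z, cd$batch, cd$cell_type, seed = 1)
#> [1] 0.8874074
batch_entropy(pca_embed(prep), cd$batch, cd$cell_type, seed = 1)
#> [1] 0.2766173
```

The learned representation recovers the simulated cell types (Leiden ARI
0.84 against ground truth) while mixing the three batches far better than
the unintegrated PCA baseline (batch entropy 0.89 vs 0.28; 1 would be
perfect local mixing). Leave-one-batch-out label transfer on the same
embedding reaches macro F1 ≈ 0.94.

A command-line front end over the same functions lives at
`inst/cli/sctwin.R` with subcommands `simulate`, `preprocess`, `train`,
`embed`, `eval-integration`, `label-transfer` and `run` (full pipeline
from a YAML config). Datasets interchange as MTX + TSV triplet
directories.

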