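# scregnet

Gene regulatory network (GRN) inference from single-cell or bulk
expression data with an edge-aware graph transformer variational
autoencoder.

## The problem

Reconstructing which transcription factors (TFs) regulate which target
genes from expression data alone is a core problem in systems biology.
Co-expression captures association but not direction, and scRNA-seq
matrices are high-dimensional, sparse and noisy, so models trained on
whole networks overfit easily. `scregnet` addresses this with a
subgraph-based pipeline:

1. **Co-expression network (GCEN).** Expression is variance-stabilised
   with the inverse hyperbolic sine, all pairwise Pearson correlations
   are computed across cells, and gene pairs with `|r| > 0.1` become
   edges with signed weights.
2. **TF-anchored subgraph sampling.** For each TF, the neighbourhood is
   expanded hop by hop until at least 99 neighbours are collected; in
   training a single uniform draw fixes the subgraph to 100 nodes, while
   at inference deterministic chunks cover every collected neighbour.
3. **Expression transcoder.** Each gene's profile (cells plus a binary
   TF flag, z-scored per cell *within* the subgraph so gene identity
   cannot be memorised) is lifted by a kernel-1 convolution and a
   single-layer 4-head transformer, then mean-pooled into a fixed
   64-dimensional embedding, independent of cell count.
4. **Graph transformer VAE.** Stacked blocks compute edge-aware pairwise
   attention, `a_ij = softmax(q_i · (k_j + W_e e_ij) / sqrt(d))`, over
   the subgraph; the encoder emits a 16-dimensional Gaussian posterior
   for nodes and edges, latents are sampled by reparameterisation
   (`z = mu + sigma * eps`), and a decoder plus sigmoid inner-product
   head reconstructs a probabilistic adjacency matrix.
5. **Training.** Balanced dynamic negative sampling per epoch, summed
   binary cross-entropy plus `beta * KL` with `beta = 1/#genes`, Adam
   (lr 0.001, batch 8), plateau learning-rate decay, early stopping,
   L1 regularisation.
6. **Aggregation and evaluation.** Per-subgraph predictions above 0.3
   are weighted (TF-initiated edges doubled), averaged over contributing
   subgraphs and min–max normalised into a ranked global GRN; evaluation
   offers sampled (100× bootstrapped 1:1 negatives from a clean pool) and
   full-matrix AUROC/AUPRC plus early precision.

A synthetic-data module generates ground-truth GRNs and matching
expression (linear-Gaussian propagation, softplus counts, dropout zeros)
so the entire pipeline is trainable and testable without any downloads.

## Worked example

```r
library(scregnet)

ds  <- simulate_dataset(synthetic_spec(seed = 1))   # 150 genes, 15 TFs, 300 cells
net <- build_gcen(ds$expr, threshold = 0.1)
net
#> coexpression_network: 150 genes, 1344 edges (|r| > 0.1), 15 TFs

split <- make_benchmark_split(ds, seed = 1)
cfg   <- run_config(seed = 1)
set.seed(cfg$seed)
gt    <- rbind(split$train, split$val)
train <- prepare_subgraphs(net, ds$expr, gt, split$train_tfs, cfg)
val   <- prepare_subgraphs(net, ds$expr, gt, split$val_tfs, cfg)
fit   <- train_model(grn_model_init(cfg), train, val, gt, epochs = 30)
grn   <- infer_grn(fit$model, ds$expr, tfs = split$test_tfs, net = net)
head(grn, 3)
#>   source target     score n_subgraphs
#> 1   TF02   G096 1.0000000           3
#> 2   TF07   G096 0.9999746           2
#> 3   TF08   G096 0.9998656           3
```

Evaluating the held-out TFs against the known synthetic truth (seed 1)
prints, via `run_benchmark()`:

```
sampled AUROC: 0.998   sampled AUPRC: 0.997
baseline (absolute-correlation) AUROC: 0.990
full-matrix AUROC: 0.997
```

i.e. the model separates true held-out regulatory edges from clean
negatives almost perfectly and outperforms the symmetric co-expression
ranking, which cannot use TF identity or direction.

## Command line

A thin wrapper over the same functions is installed at
`inst/exec/scregnet`:

```sh
Rscript <pkg>/exec/scregnet simulate   --out data --seed 1
Rscript <pkg>/exec/scregnet build-gcen --expr data/expression.tsv --out gcen
Rscript <pkg>/exec/scregnet train      --expr data/expression.tsv \
    --tfs data/tfs.txt --truth data/ground_truth.tsv --out run
Rscript <pkg>/exec/scregnet infer      --model run/checkpoint.rds \
    --expr data/expression.tsv --tfs data/tfs.txt --out out
Rscript <pkg>/exec/scregnet evaluate   --pred out/grn.tsv \
    --truth data/ground_truth.tsv --out report
```

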