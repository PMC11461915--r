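# jivebatch

Batch-effect correction for multi-batch single-cell RNA-seq using the
JIVE decomposition (joint and individual variation explained), together
with the quantitative evaluation suite used to benchmark such
corrections (kBET, average silhouette width, local inverse Simpson's
index, PVCA) and a Splat-style multi-batch count simulator.

## Who this is for

Analysts integrating scRNA-seq batches who want a *linear, directly
interpretable* correction: unlike anchor- or cluster-based integration,
JIVE is a dimension-reduction model with an explicit mapping between the
original and corrected data, and the variation it removes is retained in
inspectable per-batch components rather than discarded.

## The model

Each batch's cells x genes matrix (`Y_i = t(X_i)`, all batches sharing
one gene axis — horizontal integration) is decomposed as

```
Y_i = U_i S + W_i S_i + R_i ,        S S_i' = 0 for every batch i
```

* `U_i S` — **joint structure**: a rank-`r` signal whose gene-space basis
  `S` is common to all batches; read as biology.
* `W_i S_i` — **individual structure**: rank-`r_i`, batch-specific,
  constrained orthogonal to the joint basis; read as technical batch
  effect.
* `R_i` — residual noise.

The fit alternates exact least-squares updates (truncated SVDs) for the
two blocks, individual structure first, minimizing the total squared
residual; the corrected expression matrix is `t(U_i S)` and the joint
scores `U` double as a low-dimensional embedding for downstream
analysis. Ranks can be fixed (`joint 10, individual 20` is the
simulation default) or chosen by a permutation test on singular values.

## Worked example

Simulate two batches with a strong batch effect and three cell types,
correct them, and score the correction:

```r
library(jivebatch)

cfg <- simulation_config(n_genes = 1000, cells_per_batch = c(200, 200),
                         de_location = 0.75, batch_location = 0.75,
                         libsize_location = 8, seed = 1)
sim <- simulate_counts(cfg)
sim$collection
#> BatchCollection: 1000 genes, 2 batches, 400 cells (counts space)
#>   batch1: 200 cells
#>   batch2: 200 cells
#>   cell types: type1, type2, type3

norm  <- log_normalize(sim$collection)       # counts per 10k, log1p
cen   <- center_batches(norm)                # pooled gene centering
model <- fit_jive(cen$collection, joint_rank = 10, individual_ranks = 20,
                  tol = 1e-5, max_iter = 60, gene_means = cen$gene_means)
model
#> JIVEModel: 2 batches, 400 cells x 1000 genes
#>   joint rank 10; individual ranks 20, 20
#>   60 iterations, converged: FALSE, final SSE 159151

variance_explained(model, cen$collection)
#>    batch      joint individual  residual
#> 1 batch1 0.06415856  0.3928214 0.5427219
#> 2 batch2 0.06440793  0.3894851 0.5458205

batch <- rep(cen$collection$batch_labels, c(200, 200))
types <- unlist(cen$collection$cell_types)
raw_embedding  <- pca_embed(do.call(cbind, cen$collection$matrices), d = 30,
                            batch = batch, cell_type = types)
jive_embedding <- joint_embedding(model)

kbet_acceptance(raw_embedding,  0.05, seed = 1)   #> 0
kbet_acceptance(jive_embedding, 0.05, seed = 1)   #> 0.95

asw_report(raw_embedding,  seed = 1)[c("asw_batch", "asw_cell")]
#> batch 0.498, cell type 0.078
asw_report(jive_embedding, seed = 1)[c("asw_batch", "asw_cell")]
#> batch 0.001, cell type 0.217
```

Reading the numbers: the strong batch effect lands almost entirely in
the *individual* structures (~39% of each batch's variance) while the
joint structure (~6%) carries the shared cell-type signal. On the raw
30-PC embedding every kBET neighborhood fails the chi-squared test
(acceptance 0) and batches form separated silhouette clusters
(ASW batch 0.50); on the JIVE joint scores the batches are statistically
well mixed (kBET acceptance 0.95, ASW batch ~0) while cell-type
resolution *improves* (ASW cell type 0.078 -> 0.217), because the batch
direction no longer dominates the embedding. `converged: FALSE` here
only means the 60-iteration demo cap stopped the fit before the 1e-5
tolerance; the structures are stable at metric precision.

## Command line

```sh
Rscript inst/cli/jivebatch.R simulate --out data/ --genes 5000 \
    --cells 500,500 --de-location 0.5 --batch-location 0.5 --seed 1
Rscript inst/cli/jivebatch.R run --config run.json
```

`run.json` is the JSON form of the `run_pipeline()` configuration
(input source, preprocessing, ranks or `"permutation"`, metric list,
output directory, seed); every artifact — model archive, corrected
matrix, joint scores, metrics JSON, run manifest — is written to the
output directory and is bit-reproducible given the seed.

## What is deliberately out of scope

Wrappers for other integration tools (Seurat, Harmony, LIGER,
Combat-seq), BIC rank selection, AJIVE, zero-inflated/negative-binomial
JIVE variants, and t-SNE/UMAP internals. See the methods vignette
(`vignettes/jive-batch-correction.Rmd`) for the model's assumptions,
parameter guidance and known limitations, including when JIVE should
*not* be used (strongly unbalanced batches, batch effects confounded
with biology).
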