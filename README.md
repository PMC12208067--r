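# gsi — Gene Spatial Integration for multi-sample spatial transcriptomics

`gsi` integrates multiple 10x-Visium-style spatial transcriptomics samples
by treating **each gene's spatial distribution as an image**. Most spatial
clustering tools lean on spot *proximity*; `gsi` instead extracts a global
per-gene *distribution* feature and fuses it with the expression assay, so
downstream single-cell tooling (PCA, SNN + Louvain clustering) sees both
what a gene expresses and **where** it expresses. Because multi-sample
integration amplifies batch effects, the pipeline pairs the augmented assay
with a mutual-nearest-pair, PC-rejection batch corrector plus an optional
empirical-Bayes (ComBat-style) pre-correction.

It is aimed at analysts with several Visium sections of the same tissue
(e.g. cortical slabs with annotated layers) who want one integrated,
batch-corrected embedding and spatial-domain labels, plus the standard
integration benchmarking metrics to judge the result.

## The method

For each sample with log-normalized expression matrix `M` (genes × spots,
Seurat `LogNormalize` convention, scale factor 10⁴):

1. **Rasterize** — each gene `i` becomes a binary image `P` on the Visium
   array grid, `p_xy = 1` iff `m_ij > 0` at the spot with array
   coordinates `(x, y)`, resized to a fixed 220 × 280 raster by
   nearest-neighbour mapping (`src = floor((dst + 0.5)·src/dst)`), so the
   operation is bit-reproducible.
2. **Embed** — an autoencoder (dense, seeded, trained by minimizing the
   mean over genes of per-image pixel MSE, `L_recon = (1/N_gene) Σ ‖P_i −
   P'_i‖²`) compresses each image into a latent vector; stacking them gives
   the spatial embedding `H` (genes × d).
3. **Augment & integrate** — `A = [M | H]` per sample, then
   `C = [A_1 A_2 … A_N]` across samples. Embedding columns ride along as
   batch-labelled pseudo-columns.
4. **Batch-correct** — optionally ComBat-correct `C`; select `GN` variable
   genes; PCA over columns; cluster each batch's columns into `GNUM`
   groups (seeded k-means); match mutually-nearest group centroids across
   batches; **reject principal components whose paired-centroid correlation
   is poor** (a batch-driven PC varies between pair members, a biological
   PC agrees). Defaults: `GNUM = 50`, `PCNUM = 30`, `ROUND = 2`,
   `GN = 1500`, `SEED = 1`, ComBat on.
5. **Cluster & evaluate** — SNN graph (k = 20, Jaccard weights, prune
   1/15) + Louvain with a resolution grid search; metrics: ARI, NMI,
   ASW, cLISI, isolated F1/ASW (bio-conservation) and batch ASW, graph
   connectivity, iLISI, kBET (batch mixing).

## Worked example

No downloads needed — the package ships a generator that emulates a
layered tissue (horizontal bands as cortical layers + a white-matter band,
10 marker genes per layer) across 3 batches with a planted batch effect:

```r
library(gsi)
sim <- synth_generate(synth_config(seed = 7))     # 3 samples, 40x60 spots, 300 genes
cfg <- pipeline_config(arm = "spatial+beer", raster_target = c(55, 70),
                       ae = list(latent_dim = 32L, hidden = c(64L), epochs = 25L),
                       cluster = list(grid = seq(0.2, 1.2, 0.2)), seed = 7)
man <- run_pipeline(sim$samples, cfg)
print(man$corrected); print(man$clusters); print(man$metrics)
```

which prints (about two minutes on one CPU):

```
CorrectedResult: 300 genes x 7296 columns; 4 of 30 PCs retained: 2 3 4 5
ClusterResult: 7 clusters at resolution 0.2 (selection score 0.5582)
MetricReport ( 7200 cells, 5 labels, 3 batches )
               ari                nmi           asw_cell              clisi
            0.5582             0.5149             0.6003             0.8632
            iso_f1            iso_asw          batch_asw graph_connectivity
            0.7978             0.5606             0.9831             1.0000
             ilisi    kbet_acceptance
            0.8600             0.9614
```

Reading it: the corrector kept 4 of 30 PCs (the rejected ones carried the
planted batch signal — PC 1 here was batch-dominated); clustering those
PCs recovers the 5 planted layers at ARI 0.56, while batch-mixing scores
(iLISI 0.86, kBET acceptance 0.96) show the three batches interleaved.
Running the same data with `arm = "base"` or `arm = "spatial"` (no
correction) drops ARI to ≈ 0 because clusters collapse onto batches —
the ablation that motivates combining spatial augmentation *with* batch
removal.

A command-line front end with `synth`, `preprocess`, `run` and `eval`
subcommands lives at `inst/cli/gsi.R` (JSON config; see the vignette).

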