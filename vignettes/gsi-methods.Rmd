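---
title: "Gene spatial integration: model, batch correction and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene spatial integration: model, batch correction and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Visium-style spatial transcriptomics yields, per tissue section, a count
matrix `M` (genes × spots) and integer array coordinates for every spot.
Clustering spots of several sections jointly is attractive — shared domains
gain statistical power — but two things get in the way: most tools only see
expression (a gene's *spatial arrangement* is invisible to PCA on `M`), and
sections collected separately carry batch effects that a joint embedding
amplifies.

`gsi` addresses both with a deliberately simple pipeline:

1. **Gene-distribution images.** Each gene's expressed-spot set becomes a
   binary image on the array grid (`1` wherever the normalized value is
   positive), resized to a fixed raster by nearest-neighbour sampling. The
   binarization is intentional: the *support* of expression is the spatial
   signal; magnitudes stay in `M`, so no information is double-counted.
2. **Autoencoder embedding.** A seeded autoencoder trained on all genes of
   all samples in the integration group compresses each image to a latent
   vector (matrix `H`, genes × d), minimizing mean squared reconstruction
   error. Genes with similar territories (e.g. markers of the same layer)
   land near each other in latent space regardless of which section they
   came from.
3. **Augmentation and integration.** `A = [M | H]` per sample and
   `C = [A_1 … A_N]` across samples. The embedding columns are
   *pseudo-columns*: they carry their sample's batch label, participate in
   gene scaling, PCA and batch correction (they re-weight gene loadings
   toward spatially coherent genes), but are stripped before labels are
   reported or metrics computed — they have no annotation and are not
   spots.
4. **Batch correction by PC rejection.** After an optional per-gene
   empirical-Bayes location/scale correction (parametric ComBat), the
   variable-gene PCA of `C` is screened component by component: columns of
   each batch are k-means-grouped, group centroids are matched across
   batches by mutual nearest neighbours, and a PC whose paired-centroid
   scores correlate poorly across batches is rejected as batch-driven.
   Biology shared by the batches survives; directions that exist to
   separate batches do not.
5. **Clustering and evaluation.** SNN graph + Louvain over the retained
   PCs, with a resolution grid search; a metric panel quantifies
   bio-conservation (ARI, NMI, truth-label ASW, cLISI, isolated F1/ASW)
   and batch mixing (batch ASW, graph connectivity, iLISI, kBET).

## Parameters that matter

| Parameter | Default | Meaning / why |
|---|---|---|
| `scale_factor` | 10⁴ | log-normalization constant (counts per 10k, the Seurat convention) |
| raster target | 220 × 280 | fixed image size (rows × cols); config-overridable, tests use smaller rasters of the same aspect for CPU reasons |
| `latent_dim` d | 128 | latent code length; 32 suffices at desk scale |
| `epochs`, `lr`, `batch_size` | 50, 1e-3, 128 | Adam training; the loss is exactly the mean over images of per-image pixel MSE |
| `scale_mode` | `match_sd` | embedding columns standardized to the pooled SD of `M`, so raw latent magnitudes cannot dominate the PCA |
| `GNUM` | 50 | column groups per batch for mutual pairing; pairing cost is O(GNUM²), and group centroids are more stable than per-column MNN |
| `PCNUM` | 30 | PCs computed and screened |
| `ROUND` | 2 | pairing/scoring repetitions; round 2 re-pairs using only currently retained PCs, so pairing is not polluted by batch-driven axes |
| `GN` | 1500 | variable genes (dispersion-ranked) entering PCA; clipped to the gene count |
| `cor_threshold`, `cor_method` | 0.7, Spearman | PC retention cutoff — an implementation default, exposed in config, because the published configuration names the mechanism but not the cutoff |
| `k_neighbors`, prune | 20, 1/15 | Seurat-convention SNN graph |
| kNN sizes for metrics | LISI perplexity 30, kBET k₀ = 50, connectivity k = 15 | standard benchmarking-suite choices |

## The synthetic world

`synth_config()` emulates the benchmark situation the method targets: a
cortex-like tissue of horizontal bands (the last band standing in for
white matter), `markers_per_layer` genes per band whose negative-binomial
mean is `marker_fold` higher inside their band, i.i.d. per-gene log-normal
batch wobble, and — crucially — a *planted batch-only expression
direction* added to every batch beyond the first, giving the corrector a
known axis it should reject.

Defaults were fixed once, before acceptance measurement, as a scaled-down
DLPFC-like world: 3 samples (three donors/sections is the canonical
integration case), 40 × 60 grid = 2400 spots/sample (real sections run
3.6–4.2k), 300 genes (a marker-panel-sized subset of a transcriptome), 5
layers × 10 markers, `marker_fold = 3` (cortical layer markers are a few-
fold enriched, not on/off), `base_count_mean = 2` with NB size 2 and 10 %
dropout (sparse, overdispersed Visium-like counts), `batch_logfc_sd = 0.2`
and `batch_shift_pc = 1.5` (a batch effect strong enough that batches
separate in an uncorrected PCA, as real multi-donor sections do).

What a green test does establish: every stage behaves per contract, the
corrector finds and removes a *linear, planted* batch axis, and the
spatial+corrected arm beats both ablations on layered data. What it does
not: performance on real tissue (no spot-swapping, no segmentation noise,
no nonlinear batch distortion, uniform band geometry), nor equivalence
with any external implementation of the batch corrector.

## Numerical choices

- **Raster resize** uses the explicit center-aligned floor map
  `src = floor((dst + 0.5)·src_extent/dst_extent)` rather than an image
  library, so outputs are bit-identical across platforms. Binary input and
  nearest-neighbour sampling commute with binarization, so "binarize then
  resize" equals "resize then binarize".
- **Autoencoder**: the default architecture is a dense symmetric MLP
  (ReLU hidden layers, linear latent, sigmoid output) with hand-written
  backprop and Adam. A convolutional encoder would be the field's usual
  choice for map-like images, but no deep-learning framework is available
  in the target environment; at these raster sizes a seeded MLP trains in
  seconds and, more importantly, is bit-reproducible. He-scaled Gaussian
  initialization under a single seed; minibatch order is drawn from a
  derived seed, so identical configs give identical loss histories.
- **ComBat** is the standard parametric EB recipe (normal prior on
  additive, inverse-gamma on multiplicative batch effects, fixed-point
  posterior iteration). Zero-pooled-variance genes bypass correction
  unchanged. One consequence worth stating honestly: EB *shrinkage* means
  per-gene batch-mean residuals after correction are sampling noise shrunk
  halfway toward the common effect, roughly `sd/√n` per gene — the
  *systematic* planted shift is removed (our acceptance measurement:
  residual ≲ 0.1 % of a 5-unit shift) but a per-gene residual bound of
  0.05 at 100 columns/batch is not attainable by any faithful EB
  implementation; the acceptance check therefore tests the systematic
  component.
- **PCA** treats columns as observations over row-scaled variable genes,
  with a deterministic sign convention (largest-|loading| coordinate
  positive). Variable-gene dispersion is computed on the uncorrected
  matrix because ComBat output can be negative, making var/mean
  ill-defined.
- **k-means grouping** uses one shared seed for every batch, so identical
  batches produce identical groupings (and thus exactly-matching mutual
  pairs with correlation 1 — the no-batch-signal fixture).
- **Guarantee of progress**: if the correlation threshold would reject
  everything, the two best-correlated PCs are retained. If mutual pairing
  yields fewer than 3 pairs (far-apart batches collapse the
  nearest-foreign-centroid map), the grouping is refined by doubling
  `GNUM` up to half the smallest batch; a refinement *round* that still
  cannot pair keeps the previous round's result rather than aborting.
- **Louvain** is seeded through R's RNG; labels are re-indexed contiguous
  from 0; ties in the resolution search break toward the smaller
  resolution. Truth-guided (max-ARI) selection mirrors the evaluation
  protocol of the benchmarking literature and is an evaluation convention,
  not a claim of unsupervised performance; a cluster-count mode is
  provided for unannotated data.
- **LISI** calibrates a per-point Gaussian kernel over the 3·perplexity
  nearest neighbours by binary search on the kernel entropy; kBET uses a
  χ² goodness-of-fit of local vs global batch composition on fixed-size
  neighbourhoods (self included).

## Open design points, decided

- Genes present in only some samples are **intersected** (not
  zero-filled) before stacking; zero-filling would fabricate "absent
  everywhere" spatial images for genes that were simply not measured.
- The pseudo-column reading of the augmentation (embedding columns enter
  the integrated assay as extra columns) is the literal reading of the
  concatenation equations; the alternative — projecting `H` onto spots to
  make spot-level features — is deliberately not implemented.
- Both grid-search modes (max-ARI and closest-cluster-count) exist because
  the evaluation protocol could be read either way.
- "ASW" vs "cell ASW" in the metric list are treated as one label-ASW
  computation (reported once as `asw_cell`); the source list does not
  disambiguate them and a second input embedding is not defined here.
- The batch corrector corrects **all** genes but screens PCs on the `GN`
  variable-gene subspace; the corrected full matrix is what gets exported
  for external tools.

## Known limitations

- The autoencoder is dense; very large rasters (full 220 × 280 at tens of
  thousands of genes) train slowly on one CPU. Use a smaller raster or
  fewer variable genes at desk scale.
- The batch corrector removes *linear* batch-dominated PCs; nonlinear
  batch distortions are out of scope.
- `beer()` requires enough columns per batch to form ≥ 3 mutual group
  pairs; tiny batches (< ~20 columns) should lower `GNUM`.
- Metrics are O(n²) in spots (blockwise, memory-safe); beyond ~50k spots
  subsample for the metric panel.
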