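test_that("generator is deterministic and respects config invariants", {
  cfg <- synth_config(n_samples = 2, grid = c(10L, 12L), n_genes = 60,
                      markers_per_layer = 5, n_layers = 3, seed = 42)
  g1 <- synth_generate(cfg)
  g2 <- synth_generate(cfg)
  expect_identical(as.matrix(g1$samples[[1]]$counts),
                   as.matrix(g2$samples[[1]]$counts))
  expect_identical(g1$samples[[2]]$region_labels,
                   g2$samples[[2]]$region_labels)
  expect_equal(length(g1$samples), 2)
  expect_equal(nrow(g1$samples[[1]]$counts), 60)
  expect_equal(ncol(g1$samples[[1]]$counts), 120)
  expect_setequal(unique(g1$samples[[1]]$region_labels),
                  c("layer_1", "layer_2", "WM"))

  expect_error(synth_config(n_layers = 1), "n_layers")
  expect_error(synth_config(n_genes = 10, markers_per_layer = 10,
                            n_layers = 5), "exceeds")
  expect_error(synth_config(dropout = 1), "dropout")
})

test_that("marker enrichment matches marker_fold within 10%", {
  cfg <- synth_config(n_samples = 1, grid = c(40L, 40L), n_genes = 100,
                      markers_per_layer = 6, n_layers = 4, marker_fold = 3,
                      batch_shift_pc = 0, batch_logfc_sd = 0, dropout = 0,
                      seed = 7)
  g <- synth_generate(cfg)
  s <- g$samples[[1]]
  counts <- as.matrix(s$counts)
  lay <- g$truth$spot_layer
  for (l in 1:2) {
    gi <- which(g$truth$marker_layer == l)
    inside <- mean(counts[gi, lay == l])
    outside <- mean(counts[gi, lay != l])
    expect_equal(inside / outside, 3, tolerance = 0.1)
  }
})

test_that("null config (no markers' batch effects) is well mixed on raw PCA", {
  cfg <- synth_config(n_samples = 2, grid = c(24L, 30L), n_genes = 100,
                      markers_per_layer = 5, n_layers = 2,
                      marker_fold = 1.0001,  # effectively flat
                      batch_logfc_sd = 0, batch_shift_pc = 0, dropout = 0,
                      seed = 9)
  g <- synth_generate(cfg)
  s <- align_genes(lapply(g$samples, function(x) lognormalize(filter_spots(x))))
  augs <- lapply(s, function(x) augment(as.matrix(x$M), NULL,
                                        sample_id = x$sample_id))
  im <- suppressWarnings(integrate_samples(augs))
  emb <- gsi:::pca_embedding(im, beer_params(PCNUM = 10, GN = 100))
  expect_gt(kbet(emb, im$batch_labels, k0 = 50)$acceptance, 0.9)
})

test_that("batch shift separates batches before correction", {
  g <- small_sim(seed = 13)
  s <- align_genes(lapply(g$samples, function(x) lognormalize(filter_spots(x))))
  augs <- lapply(s, function(x) augment(as.matrix(x$M), NULL,
                                        sample_id = x$sample_id))
  im <- integrate_samples(augs)
  emb <- gsi:::pca_embedding(im, beer_params(PCNUM = 10, GN = 120))
  expect_lt(kbet(emb, im$batch_labels, k0 = 50)$acceptance, 0.5)
})

test_that("same-layer marker images are more alike than cross-layer (Jaccard)", {
  cfg <- synth_config(n_samples = 1, grid = c(20L, 24L), n_genes = 80,
                      markers_per_layer = 5, n_layers = 4, marker_fold = 4,
                      base_count_mean = 0.3, dropout = 0, batch_shift_pc = 0,
                      seed = 21)
  g <- synth_generate(cfg)
  s <- lognormalize(filter_spots(g$samples[[1]]))
  st <- rasterize_sample(s, target = c(20L, 24L))
  jac <- function(a, b) sum(a & b) / sum(a | b)
  ml <- g$truth$marker_layer[match(st$gene_ids, names(g$truth$marker_layer))]
  within <- c(); across <- c()
  idx <- which(!is.na(ml))
  for (i in idx) for (j in idx) {
    if (i >= j) next
    v <- jac(st$images[i, , ], st$images[j, , ])
    if (ml[i] == ml[j]) within <- c(within, v) else across <- c(across, v)
  }
  expect_gt(mean(within), mean(across))
})

test_that("generated samples round-trip through the visium reader", {
  g <- synth_generate(synth_config(n_samples = 1, grid = c(6L, 8L),
                                   n_genes = 30, markers_per_layer = 3,
                                   n_layers = 2, seed = 3))
  dir <- withr::local_tempdir()
  write_visium(g$samples[[1]], dir)
  s2 <- read_visium(dir, file.path(dir, "tissue_positions.csv"))
  expect_identical(as.matrix(s2$counts), as.matrix(g$samples[[1]]$counts))
})
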