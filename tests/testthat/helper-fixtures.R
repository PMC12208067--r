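# Shared fixtures, built in code at test time.

# A tiny deterministic sample: explicit counts and coordinates.
tiny_sample <- function(sample_id = "tiny") {
  counts <- matrix(c(3, 0, 7, 0, 1,
                     0, 0, 2, 0, 4), nrow = 2, byrow = TRUE)
  barcodes <- paste0("bc", 1:5)
  st_sample(sample_id, counts,
            gene_ids = c("geneA", "geneB"), barcodes = barcodes,
            coords = data.frame(barcode = barcodes,
                                array_row = c(0L, 0L, 1L, 1L, 2L),
                                array_col = c(0L, 1L, 0L, 1L, 0L)))
}

# Small random sample on a grid, seeded.
random_sample <- function(seed, n_genes = 20, rows = 6, cols = 8,
                          sample_id = paste0("s", seed)) {
  withr::with_seed(seed, {
    n_spot <- rows * cols
    counts <- matrix(rpois(n_genes * n_spot, 2), n_genes, n_spot)
    barcodes <- sprintf("%s_bc%03d", sample_id, seq_len(n_spot))
    g <- expand.grid(array_row = 0:(rows - 1), array_col = 0:(cols - 1))
    st_sample(sample_id, counts,
              gene_ids = sprintf("g%03d", seq_len(n_genes)),
              barcodes = barcodes,
              coords = data.frame(barcode = barcodes,
                                  array_row = g$array_row,
                                  array_col = g$array_col))
  })
}

# Independent brute-force oracle for the rasterizer: enumerate every output
# pixel and apply the index map directly.
raster_oracle <- function(m_row, coords, target) {
  nr <- max(coords[, 1]) + 1L
  nc <- max(coords[, 2]) + 1L
  g <- matrix(0L, nr, nc)
  for (j in seq_along(m_row)) {
    if (m_row[j] > 0) g[coords[j, 1] + 1L, coords[j, 2] + 1L] <- 1L
  }
  out <- matrix(0L, target[1], target[2])
  for (i in seq_len(target[1])) for (jj in seq_len(target[2])) {
    sr <- floor((i - 1 + 0.5) * nr / target[1]) + 1L
    sc <- floor((jj - 1 + 0.5) * nc / target[2]) + 1L
    out[i, jj] <- g[sr, sc]
  }
  out
}

# Brute-force ARI over all point pairs (independent of the contingency
# table implementation).
ari_oracle <- function(a, b) {
  n <- length(a)
  ss <- sd_ <- ds <- dd <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) ss <- ss + 1
    else if (sa && !sb) sd_ <- sd_ + 1
    else if (!sa && sb) ds <- ds + 1
    else dd <- dd + 1
  }
  tot <- ss + sd_ + ds + dd
  exp_idx <- (ss + sd_) * (ss + ds) / tot
  max_idx <- ((ss + sd_) + (ss + ds)) / 2
  if (max_idx == exp_idx) return(1)
  (ss - exp_idx) / (max_idx - exp_idx)
}

# Mutual-information NMI oracle via direct probability enumeration.
nmi_oracle <- function(a, b) {
  n <- length(a)
  pa <- table(a) / n; pb <- table(b) / n
  mi <- 0
  for (x in names(pa)) for (y in names(pb)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (pa[[x]] * pb[[y]]))
  }
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / ((ha + hb) / 2)
}

# Three well-separated Gaussian blobs in 2-D.
blob_embedding <- function(n_per = 100, sep = 50, sd = 1, seed = 7) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, sep, 0, 0, sep), ncol = 2, byrow = TRUE)
    x <- do.call(rbind, lapply(1:3, function(k)
      cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))))
    list(x = x, labels = rep(1:3, each = n_per))
  })
}

# Small synthetic multi-sample dataset for integration-level tests.
small_sim <- function(seed = 5, n_samples = 2, batch_shift = 1.5) {
  synth_generate(synth_config(n_samples = n_samples, grid = c(16L, 24L),
                              n_genes = 120L, markers_per_layer = 8L,
                              n_layers = 4L, batch_shift_pc = batch_shift,
                              seed = seed))
}

# Planted batch-axis simulation shared by the BEER unit tests and the
# acceptance suite: two batches with common two-component biology plus a
# batch-exclusive expression direction of known loading w.
planted_axis_sim_acc <- function(seed, n_gene = 60, n_per = 80, shift = 6) {
  withr::with_seed(seed, {
    comp <- rep(1:2, times = n_per / 2)
    bio <- matrix(rnorm(n_gene * 2, sd = 2), n_gene, 2)
    X1 <- bio[, comp] + matrix(rnorm(n_gene * n_per), n_gene, n_per)
    X2 <- bio[, comp] + matrix(rnorm(n_gene * n_per), n_gene, n_per)
    w <- rnorm(n_gene); w <- w / sqrt(sum(w^2))
    X2 <- X2 + w * shift
    X <- cbind(X1, X2) + 10
    rownames(X) <- sprintf("g%03d", seq_len(n_gene))
    list(X = X, batch = rep(c("b1", "b2"), each = n_per), w = w)
  })
}
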