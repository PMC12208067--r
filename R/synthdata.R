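#' Configuration for the synthetic layered-tissue generator
#'
#' The generator emulates a small multi-sample Visium experiment over a
#' layered tissue (horizontal bands standing in for cortical layers, the
#' last band playing white matter): each layer owns a set of marker genes
#' whose negative-binomial mean is `marker_fold` times higher inside the
#' layer, every batch carries i.i.d. per-gene multiplicative wobble, and
#' batches beyond the first get a planted batch-only expression direction
#' so correction methods have a known axis to remove.
#'
#' Defaults are sized for a desk-scale run: 3 samples, a 40 x 60 grid
#' (2400 spots), 300 genes, 5 layers x 10 markers.
#'
#' @param n_samples Number of samples/batches.
#' @param grid Integer pair (rows, cols) of the spot lattice.
#' @param n_layers Number of horizontal bands (>= 2); the last band is
#'   labelled `WM`.
#' @param n_genes Total genes; `markers_per_layer * n_layers` must not
#'   exceed it.
#' @param markers_per_layer Marker genes owned by each layer.
#' @param marker_fold Mean multiplier of a marker inside its layer (> 1).
#' @param base_count_mean Baseline negative-binomial mean per gene/spot.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param batch_logfc_sd SD of the per-gene per-batch log-normal wobble.
#' @param batch_shift_pc Magnitude of the planted batch-only log-expression
#'   direction added to batches >= 2 (0 disables).
#' @param dropout Bernoulli zero-inflation probability in \[0, 1).
#' @param seed Integer seed.
#' @return A `SynthConfig` list.
#' @export
synth_config <- function(n_samples = 3L, grid = c(40L, 60L), n_layers = 5L,
                         n_genes = 300L, markers_per_layer = 10L,
                         marker_fold = 3, base_count_mean = 2,
                         dispersion = 2, batch_logfc_sd = 0.2,
                         batch_shift_pc = 1.5, dropout = 0.1, seed = 1L) {
  if (n_layers < 2) gsi_stop("n_layers must be >= 2")
  if (markers_per_layer * n_layers > n_genes)
    gsi_stop("markers_per_layer * n_layers exceeds n_genes")
  if (dropout < 0 || dropout >= 1) gsi_stop("dropout must be in [0, 1)")
  if (marker_fold <= 1) gsi_stop("marker_fold must be > 1")
  structure(list(n_samples = as.integer(n_samples), grid = as.integer(grid),
                 n_layers = as.integer(n_layers), n_genes = as.integer(n_genes),
                 markers_per_layer = as.integer(markers_per_layer),
                 marker_fold = marker_fold, base_count_mean = base_count_mean,
                 dispersion = dispersion, batch_logfc_sd = batch_logfc_sd,
                 batch_shift_pc = batch_shift_pc, dropout = dropout,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

layer_of_rows <- function(rows, n_rows, n_layers) {
  pmin(floor(rows / (n_rows / n_layers)), n_layers - 1L) + 1L
}

layer_names <- function(n_layers) {
  c(paste0("layer_", seq_len(n_layers - 1)), "WM")
}

#' Generate a synthetic multi-sample Visium-like dataset
#'
#' @param cfg A [synth_config()].
#' @return List with `samples` (list of [st_sample()] objects carrying
#'   region labels) and `truth` (marker-to-layer map, per-batch gene
#'   factors, planted shift directions, spot layer indices, and the config).
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  n_rows <- cfg$grid[1]; n_cols <- cfg$grid[2]
  n_spot <- n_rows * n_cols
  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  marker_layer <- rep(NA_integer_, cfg$n_genes)
  marker_layer[seq_len(cfg$markers_per_layer * cfg$n_layers)] <-
    rep(seq_len(cfg$n_layers), each = cfg$markers_per_layer)

  coords <- expand.grid(array_row = 0:(n_rows - 1),
                        array_col = 0:(n_cols - 1))
  coords <- coords[order(coords$array_row, coords$array_col), ]
  spot_layer <- layer_of_rows(coords$array_row, n_rows, cfg$n_layers)
  lnames <- layer_names(cfg$n_layers)

  # gene x spot matrix of layer-driven fold changes (shared across batches)
  fold <- matrix(1, cfg$n_genes, n_spot)
  for (l in seq_len(cfg$n_layers)) {
    g <- which(marker_layer == l)
    s <- which(spot_layer == l)
    fold[g, s] <- cfg$marker_fold
  }

  samples <- vector("list", cfg$n_samples)
  batch_factors <- matrix(1, cfg$n_genes, cfg$n_samples)
  shift_dirs <- matrix(0, cfg$n_genes, cfg$n_samples)
  for (b in seq_len(cfg$n_samples)) {
    sid <- sprintf("sample%02d", b)
    samples[[b]] <- with_seed(derive_seed(cfg$seed, sid), {
      bf <- exp(rnorm(cfg$n_genes, 0, cfg$batch_logfc_sd))
      batch_factors[, b] <- bf
      shift <- rep(0, cfg$n_genes)
      if (b >= 2 && cfg$batch_shift_pc > 0) {
        w <- rnorm(cfg$n_genes)
        w <- w / sqrt(sum(w^2)) * sqrt(cfg$n_genes)  # unit scale per gene
        shift_dirs[, b] <- w
        shift <- cfg$batch_shift_pc * w * 0.5
      }
      mu <- cfg$base_count_mean * fold * bf * exp(shift)
      counts <- matrix(rnbinom(length(mu), mu = as.numeric(mu),
                               size = cfg$dispersion),
                       cfg$n_genes, n_spot)
      if (cfg$dropout > 0) {
        keep <- matrix(rbinom(length(counts), 1, 1 - cfg$dropout),
                       cfg$n_genes, n_spot)
        counts <- counts * keep
      }
      barcodes <- sprintf("%s_bc%05d", sid, seq_len(n_spot))
      cdf <- data.frame(barcode = barcodes,
                        array_row = coords$array_row,
                        array_col = coords$array_col)
      st_sample(sample_id = sid, counts = counts, gene_ids = gene_ids,
                barcodes = barcodes, coords = cdf,
                region_labels = stats::setNames(lnames[spot_layer], barcodes))
    })
  }
  list(samples = samples,
       truth = list(marker_layer = stats::setNames(marker_layer, gene_ids),
                    layer_names = lnames,
                    spot_layer = spot_layer,
                    batch_factors = batch_factors,
                    shift_dirs = shift_dirs,
                    config = cfg))
}
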