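#' Pipeline configuration
#'
#' One config object drives every ablation arm: `base` (expression only),
#' `base+beer`, `spatial` (autoencoder-augmented), `spatial+beer` (the full
#' method). Arms without `spatial` skip rasterization and the autoencoder;
#' arms with `beer` require at least two samples.
#'
#' @param arm Ablation arm.
#' @param raster_target Raster dimensions for gene-distribution images.
#' @param ae List of autoencoder settings: `latent_dim`, `hidden`, `epochs`,
#'   `lr`, `batch_size`.
#' @param scale_mode Embedding-column scaling in [augment()].
#' @param beer A [beer_params()] object.
#' @param cluster List: `grid` (resolutions), `k_neighbors`, `mode`
#'   (`"ari"` for truth-guided selection or an integer target k).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(arm = c("spatial+beer", "base", "base+beer",
                                    "spatial"),
                            raster_target = c(220L, 280L),
                            ae = list(latent_dim = 128L, hidden = c(256L),
                                      epochs = 50L, lr = 1e-3,
                                      batch_size = 128L),
                            scale_mode = "match_sd",
                            beer = beer_params(),
                            cluster = list(grid = seq(0.05, 2, by = 0.05),
                                           k_neighbors = 20L, mode = "ari"),
                            seed = 1L) {
  arm <- match.arg(arm)
  ae_def <- list(latent_dim = 128L, hidden = c(256L), epochs = 50L,
                 lr = 1e-3, batch_size = 128L)
  ae <- utils::modifyList(ae_def, ae)
  cl_def <- list(grid = seq(0.05, 2, by = 0.05), k_neighbors = 20L,
                 mode = "ari")
  cluster <- utils::modifyList(cl_def, cluster)
  structure(list(arm = arm, raster_target = as.integer(raster_target),
                 ae = ae, scale_mode = scale_mode, beer = beer,
                 cluster = cluster, seed = as.integer(seed)),
            class = "PipelineConfig")
}

arm_uses_spatial <- function(arm) arm %in% c("spatial", "spatial+beer")
arm_uses_beer <- function(arm) arm %in% c("base+beer", "spatial+beer")

# Plain-PCA embedding used by the arms without batch correction: same
# variable-gene selection, scaling and PC count as the corrected route so
# the ablation compares like with like.
pca_embedding <- function(im, params) {
  vg <- select_variable_genes(im$C, params$GN)
  S <- scale_rows(im$C[vg, , drop = FALSE])
  npc <- min(params$PCNUM, ncol(S) - 1L, nrow(S))
  pca_columns(S, npc)$scores
}

#' Run the full integration pipeline on a list of samples
#'
#' Executes read -> filter -> normalize -> align -> \[rasterize -> train ->
#' encode -> augment\] -> integrate -> \[batch-correct\] -> cluster ->
#' evaluate, according to the configured arm.
#'
#' @param samples List of [st_sample()] objects (counts populated; samples
#'   are filtered/normalized here if not already).
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory; labels (CSV), the corrected
#'   matrix (MTX + metadata), metrics and a manifest (JSON) are written.
#' @param compute_metrics Compute the metric panel (requires region
#'   labels); default TRUE when any sample carries annotations.
#' @return A run manifest list: `arm`, `integrated`, `corrected` (or NULL),
#'   `embedding`, `clusters`, `metrics`, `training` (or NULL), `config`.
#' @export
run_pipeline <- function(samples, cfg = pipeline_config(), out_dir = NULL,
                         compute_metrics = NULL) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (inherits(samples, "STSample")) samples <- list(samples)
  if (arm_uses_beer(cfg$arm) && length(samples) < 2)
    gsi_stop("arm ", cfg$arm, " requires >= 2 samples")

  samples <- lapply(samples, function(s) {
    s <- filter_spots(s)
    if (is.null(s$M)) s <- lognormalize(s) else s
  })
  samples <- align_genes(samples)

  training <- NULL
  augs <- if (arm_uses_spatial(cfg$arm)) {
    stacks <- lapply(samples, rasterize_sample, target = cfg$raster_target)
    training <- train_autoencoder(stacks,
                                  epochs = cfg$ae$epochs, lr = cfg$ae$lr,
                                  batch_size = cfg$ae$batch_size,
                                  seed = derive_seed(cfg$seed, "ae"),
                                  latent_dim = cfg$ae$latent_dim,
                                  hidden = cfg$ae$hidden)
    lapply(seq_along(samples), function(i) {
      H <- encode(stacks[[i]], training$model)
      augment(as.matrix(samples[[i]]$M), H, scale_mode = cfg$scale_mode,
              sample_id = samples[[i]]$sample_id)
    })
  } else {
    lapply(samples, function(s)
      augment(as.matrix(s$M), NULL, sample_id = s$sample_id))
  }

  im <- if (length(augs) > 1) integrate_samples(augs) else
    suppressWarnings(integrate_samples(augs))

  corrected <- NULL
  embedding <- if (arm_uses_beer(cfg$arm)) {
    corrected <- beer(im, cfg$beer)
    corrected$embedding
  } else {
    pca_embedding(im, cfg$beer)
  }

  truth_full <- rep(NA_character_, ncol(im$C))
  spot_mask <- im$column_roles == "spot"
  for (s in samples) {
    ix <- which(im$batch_labels == s$sample_id & spot_mask)
    if (!is.null(s$region_labels)) truth_full[ix] <- unname(s$region_labels)
  }

  mode <- cfg$cluster$mode
  truth_or_k <- if (identical(mode, "ari")) {
    if (all(is.na(truth_full)))
      gsi_stop("cluster mode 'ari' needs region labels; give mode = <k>")
    truth_full
  } else as.integer(mode)
  clusters <- resolution_search(embedding, truth_or_k,
                                grid = cfg$cluster$grid,
                                seed = derive_seed(cfg$seed, "louvain"),
                                k_neighbors = cfg$cluster$k_neighbors,
                                roles = im$column_roles)

  if (is.null(compute_metrics)) compute_metrics <- !all(is.na(truth_full))
  metrics <- NULL
  if (compute_metrics) {
    metrics <- metric_report(embedding[spot_mask, , drop = FALSE],
                             clusters$labels,
                             truth_full[spot_mask],
                             im$batch_labels[spot_mask])
  }

  manifest <- list(arm = cfg$arm, integrated = im, corrected = corrected,
                   embedding = embedding, clusters = clusters,
                   metrics = metrics, training = training,
                   truth = truth_full, config = cfg)
  if (!is.null(out_dir)) write_manifest(manifest, out_dir)
  invisible(manifest)
}

# Write labels, corrected matrix, metrics and a manifest JSON to disk.
write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  im <- manifest$integrated
  spot_mask <- im$column_roles == "spot"
  labs <- data.frame(column_id = im$column_ids[spot_mask],
                     sample_id = im$batch_labels[spot_mask],
                     cluster = manifest$clusters$labels,
                     region_label = manifest$truth[spot_mask])
  write.csv(labs, file.path(out_dir, "cluster_labels.csv"), row.names = FALSE)

  X <- if (is.null(manifest$corrected)) im$C else manifest$corrected$C_prime
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE),
                  file.path(out_dir, "corrected_matrix.mtx"))
  writeLines(im$gene_ids, file.path(out_dir, "genes.tsv"))
  write.csv(data.frame(column_id = im$column_ids, batch = im$batch_labels,
                       role = im$column_roles),
            file.path(out_dir, "column_metadata.csv"), row.names = FALSE)
  utils::write.table(manifest$embedding,
                     file.path(out_dir, "embedding.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(arm = manifest$arm,
               seed = manifest$config$seed,
               n_samples = length(unique(im$batch_labels)),
               n_genes = nrow(im$C), n_columns = ncol(im$C),
               resolution = manifest$clusters$resolution,
               n_clusters = manifest$clusters$n_clusters,
               retained_pcs = if (!is.null(manifest$corrected))
                 manifest$corrected$retained_pcs else NULL,
               metrics = if (!is.null(manifest$metrics))
                 unclass(manifest$metrics) else NULL,
               package_version = as.character(utils::packageVersion("gsi")))
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' One-seed ablation study on the synthetic layered world
#'
#' Generates a synthetic multi-sample dataset (defaults: the generator's
#' stated world with batch effects on) and scores three arms on it --
#' `base` (expression-only PCA), `spatial` (autoencoder-augmented,
#' uncorrected) and `spatial+beer` (augmented + batch-corrected) -- with
#' truth-guided resolution search. Also reports batch-mixing (iLISI, kBET
#' acceptance) and NMI for the pre- and post-correction spatial embeddings.
#'
#' The spatial arms share one trained autoencoder and one integrated
#' matrix; all stages are the same exported functions [run_pipeline()]
#' composes.
#'
#' @param seed Integer seed driving the generator and every stage.
#' @param synth A [synth_config()]; defaults to the stated world with this
#'   seed.
#' @param raster_target Raster size for gene images (55 x 70 here: a
#'   quarter of the full-resolution default, same aspect, sized for CPU).
#' @param ae Autoencoder settings (desk-scale defaults).
#' @param beer_par [beer_params()] used for correction and for the shared
#'   PCA route of the uncorrected arms.
#' @param grid Resolution grid for the Louvain search.
#' @param k_neighbors SNN neighbourhood size.
#' @return List with `ari` (named: base, spatial, spatial_beer), `pre` and
#'   `post` (each: ilisi, kbet, nmi), `retained_pcs`.
#' @export
run_ablation <- function(seed,
                         synth = synth_config(seed = seed),
                         raster_target = c(55L, 70L),
                         ae = list(latent_dim = 32L, hidden = c(64L),
                                   epochs = 25L, lr = 1e-3,
                                   batch_size = 128L),
                         beer_par = beer_params(),
                         grid = seq(0.2, 1.2, by = 0.2),
                         k_neighbors = 20L) {
  sim <- synth_generate(synth)
  samples <- align_genes(lapply(sim$samples, function(s)
    lognormalize(filter_spots(s))))

  truth_of <- function(im) {
    tr <- rep(NA_character_, ncol(im$C))
    for (s in samples) {
      ix <- which(im$batch_labels == s$sample_id & im$column_roles == "spot")
      tr[ix] <- unname(s$region_labels)
    }
    tr
  }
  cl_seed <- derive_seed(seed, "louvain")
  score_arm <- function(emb, im) {
    truth <- truth_of(im)
    res <- resolution_search(emb, truth, grid = grid, seed = cl_seed,
                             k_neighbors = k_neighbors,
                             roles = im$column_roles)
    list(ari = res$score, labels = res$labels, truth = truth,
         spot = im$column_roles == "spot")
  }
  mixing <- function(emb, im, labels) {
    spot <- im$column_roles == "spot"
    e <- emb[spot, , drop = FALSE]
    ba <- im$batch_labels[spot]
    truth <- truth_of(im)[spot]
    nn <- knn_index(e, min(90L, nrow(e) - 1L))
    il <- lisi(e, ba, perplexity = 30, nn = nn)
    list(ilisi = mean((il - 1) / (length(unique(ba)) - 1)),
         kbet = kbet(e, ba, k0 = 50, nn = nn)$acceptance,
         nmi = nmi(labels, truth))
  }

  # base arm
  augs0 <- lapply(samples, function(s)
    augment(as.matrix(s$M), NULL, sample_id = s$sample_id))
  im0 <- integrate_samples(augs0)
  base_res <- score_arm(pca_embedding(im0, beer_par), im0)

  # spatial arms share the trained model and integrated matrix
  stacks <- lapply(samples, rasterize_sample, target = raster_target)
  tr <- train_autoencoder(stacks, epochs = ae$epochs, lr = ae$lr,
                          batch_size = ae$batch_size,
                          seed = derive_seed(seed, "ae"),
                          latent_dim = ae$latent_dim, hidden = ae$hidden)
  augs1 <- lapply(seq_along(samples), function(i)
    augment(as.matrix(samples[[i]]$M), encode(stacks[[i]], tr$model),
            sample_id = samples[[i]]$sample_id))
  im1 <- integrate_samples(augs1)

  emb_pre <- pca_embedding(im1, beer_par)
  spatial_res <- score_arm(emb_pre, im1)
  cr <- beer(im1, beer_par)
  sb_res <- score_arm(cr$embedding, im1)

  pre <- mixing(emb_pre, im1, spatial_res$labels)
  post <- mixing(cr$embedding, im1, sb_res$labels)

  list(ari = c(base = base_res$ari, spatial = spatial_res$ari,
               spatial_beer = sb_res$ari),
       pre = pre, post = post, retained_pcs = cr$retained_pcs)
}
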