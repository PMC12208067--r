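#' Fuse expression and spatial embeddings into an augmented matrix
#'
#' Concatenates the gene-by-spot expression matrix M with the gene-by-d
#' spatial embedding H along columns: `A = [M | H']`. Embedding columns are
#' tagged `role = "embedding"` and ride along as pseudo-columns through
#' scaling, PCA and batch correction, but are excluded from cluster-label
#' reporting and evaluation.
#'
#' @param M Gene x spot matrix (rownames = gene IDs, colnames = barcodes).
#' @param H Gene x d matrix, same genes in the same order, or `NULL`/0-column
#'   for the expression-only ("Base") arm.
#' @param scale_mode `"match_sd"` (default): each embedding column is
#'   standardized and rescaled to the pooled standard deviation of M's
#'   entries, so raw latent magnitudes cannot dominate downstream PCA;
#'   `"none"`: raw concatenation.
#' @param sample_id Sample identifier; defaults to attributes on M.
#' @return An `AugmentedMatrix`: list with `A`, `column_roles`,
#'   `column_ids`, `sample_id`, `n_spot`, `d`.
#' @export
augment <- function(M, H = NULL, scale_mode = c("match_sd", "none"),
                    sample_id = "sample") {
  scale_mode <- match.arg(scale_mode)
  M <- as.matrix(M)
  if (inherits(H, "SpatialEmbedding")) {
    sample_id <- H$sample_id
    H <- H$H
  }
  if (is.null(H)) H <- matrix(0, nrow(M), 0)
  H <- as.matrix(H)
  if (nrow(H) != nrow(M))
    gsi_stop("M and H must have the same number of genes")
  if (!is.null(rownames(M)) && !is.null(rownames(H)) && ncol(H) > 0 &&
      !identical(rownames(M), rownames(H)))
    gsi_stop("gene order mismatch between M and H; no silent reindexing")
  d <- ncol(H)
  if (d > 0 && scale_mode == "match_sd") {
    target_sd <- sd(as.numeric(M))
    H <- apply(H, 2, function(col) {
      s <- sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s * target_sd
    })
    H <- matrix(H, nrow = nrow(M))
  }
  spot_ids <- if (is.null(colnames(M))) paste0("spot_", seq_len(ncol(M)))
              else colnames(M)
  emb_ids <- if (d > 0) paste0("emb_", seq_len(d)) else character(0)
  A <- cbind(M, H)
  colnames(A) <- c(spot_ids, emb_ids)
  structure(list(A = A,
                 column_roles = c(rep("spot", ncol(M)), rep("embedding", d)),
                 column_ids = c(spot_ids, emb_ids),
                 sample_id = sample_id,
                 n_spot = ncol(M), d = d,
                 gene_ids = rownames(M)),
            class = "AugmentedMatrix")
}

#' @export
print.AugmentedMatrix <- function(x, ...) {
  cat("AugmentedMatrix", x$sample_id, ":", nrow(x$A), "genes x (",
      x$n_spot, "spots +", x$d, "embedding cols )\n")
  invisible(x)
}

#' Stack augmented samples into one integrated matrix
#'
#' Column-wise concatenation `C = [A1 A2 ... AN]` in the given sample order.
#' Every column -- including embedding pseudo-columns -- carries the batch
#' label of its originating sample; column IDs are prefixed with the sample
#' ID to guarantee uniqueness.
#'
#' @param augs List of `AugmentedMatrix` objects with identical gene order.
#' @return An `IntegratedMatrix`: list with `C`, `batch_labels`,
#'   `column_roles`, `column_ids`, `gene_ids`.
#' @export
integrate_samples <- function(augs) {
  if (inherits(augs, "AugmentedMatrix")) augs <- list(augs)
  stopifnot(length(augs) >= 1)
  if (length(augs) == 1)
    warning("integrating a single sample; batch correction will be a no-op")
  gene_ref <- augs[[1]]$gene_ids
  for (a in augs) {
    if (!identical(a$gene_ids, gene_ref))
      gsi_stop("gene sets/order differ across samples; run align_genes() ",
               "before augmenting")
  }
  C <- do.call(cbind, lapply(augs, function(a) a$A))
  batch <- unlist(lapply(augs, function(a) rep(a$sample_id, ncol(a$A))))
  roles <- unlist(lapply(augs, function(a) a$column_roles))
  ids <- unlist(lapply(augs, function(a) paste0(a$sample_id, "_", a$column_ids)))
  colnames(C) <- ids
  structure(list(C = C, batch_labels = unname(batch),
                 column_roles = unname(roles), column_ids = unname(ids),
                 gene_ids = gene_ref),
            class = "IntegratedMatrix")
}

#' @export
print.IntegratedMatrix <- function(x, ...) {
  tab <- table(x$batch_labels)
  cat("IntegratedMatrix:", nrow(x$C), "genes x", ncol(x$C), "columns;",
      length(tab), "batches (", paste(names(tab), tab, sep = "=",
                                      collapse = ", "), ")\n")
  invisible(x)
}

#' Recover one sample's expression matrix from an integrated matrix
#'
#' @param im An `IntegratedMatrix`.
#' @param batch Sample/batch label.
#' @param role Column role to keep, default `"spot"`.
#' @return The gene x column submatrix.
#' @export
slice_batch <- function(im, batch, role = "spot") {
  stopifnot(inherits(im, "IntegratedMatrix"))
  keep <- im$batch_labels == batch & im$column_roles == role
  if (!any(keep)) gsi_stop("no columns for batch ", batch, " role ", role)
  im$C[, keep, drop = FALSE]
}
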