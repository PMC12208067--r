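#' Construct a spatial transcriptomics sample
#'
#' Bundles a gene-by-spot count matrix with spot coordinates and optional
#' region annotations. The expression matrix is oriented genes x spots
#' throughout the package; writers transpose at the boundary when emitting
#' the spot-major 10x layout.
#'
#' @param sample_id Character scalar identifying the sample (used as batch
#'   label downstream).
#' @param counts Non-negative integer matrix (base or `Matrix` sparse),
#'   genes x spots.
#' @param gene_ids Character vector of feature IDs (not symbols), one per row.
#'   Must be unique.
#' @param barcodes Character vector of spot barcodes, one per column. Must be
#'   unique.
#' @param coords Data frame with columns `barcode`, `array_row`, `array_col`
#'   (integer Visium grid positions) and optionally `pixel_row`, `pixel_col`.
#' @param region_labels Optional character vector of per-spot region labels,
#'   named by barcode; `NA` marks unannotated spots.
#' @param gene_symbols Optional character vector of gene symbols (metadata
#'   only; duplicates allowed).
#'
#' @return An object of class `STSample`: a list with fields `sample_id`,
#'   `counts`, `M` (log-normalized matrix, `NULL` until
#'   [lognormalize()] is applied), `gene_ids`, `barcodes`, `coords`,
#'   `region_labels`, `gene_symbols`.
#' @export
st_sample <- function(sample_id, counts, gene_ids, barcodes, coords,
                      region_labels = NULL, gene_symbols = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) gsi_validation_error("counts must be non-negative")
  if (length(gene_ids) != nrow(counts))
    gsi_validation_error("gene_ids length != nrow(counts)")
  if (length(barcodes) != ncol(counts))
    gsi_validation_error("barcodes length != ncol(counts)")
  if (anyDuplicated(gene_ids))
    gsi_validation_error("duplicate gene IDs: ",
                         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(barcodes))
    gsi_validation_error("duplicate barcodes: ",
                         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  required <- c("barcode", "array_row", "array_col")
  if (!all(required %in% names(coords)))
    gsi_validation_error("coords must have columns barcode, array_row, array_col")
  missing_bc <- setdiff(barcodes, coords$barcode)
  if (length(missing_bc))
    gsi_validation_error("barcodes missing from coords: ",
                         paste(head(missing_bc, 5), collapse = ", "))
  coords <- coords[match(barcodes, coords$barcode), , drop = FALSE]
  rownames(coords) <- NULL
  if (any(coords$array_row < 0) || any(coords$array_col < 0))
    gsi_validation_error("array coordinates must be non-negative")
  if (!is.null(region_labels)) {
    if (is.null(names(region_labels))) {
      if (length(region_labels) != length(barcodes))
        gsi_validation_error("unnamed region_labels must match barcode count")
      names(region_labels) <- barcodes
    }
    region_labels <- region_labels[barcodes]
    names(region_labels) <- barcodes
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(sample_id = sample_id, counts = counts, M = NULL,
                 gene_ids = gene_ids, barcodes = barcodes, coords = coords,
                 region_labels = region_labels, gene_symbols = gene_symbols),
            class = "STSample")
}

#' @export
print.STSample <- function(x, ...) {
  cat("STSample", x$sample_id, ":", nrow(x$counts), "genes x",
      ncol(x$counts), "spots;",
      if (is.null(x$M)) "raw counts" else "log-normalized",
      if (is.null(x$region_labels)) "" else
        paste0("; ", sum(!is.na(x$region_labels)), " annotated spots"), "\n")
  invisible(x)
}

# Locate a file in dir allowing an optional .gz suffix.
find_mtx_file <- function(dir_path, stems) {
  for (stem in stems) for (suf in c("", ".gz")) {
    p <- file.path(dir_path, paste0(stem, suf))
    if (file.exists(p)) return(p)
  }
  gsi_io_error("missing file: ", file.path(dir_path, stems[[1]]),
               " (also tried .gz and variants)")
}

read_tsv_nohead <- function(path) {
  read.delim(path, header = FALSE, stringsAsFactors = FALSE)
}

# tissue_positions comes in two dialects: the legacy 6-column headerless CSV
# and the newer headered one (tissue_positions.csv). Both are accepted.
read_positions <- function(positions_path) {
  if (!file.exists(positions_path))
    gsi_io_error("missing file: ", positions_path)
  first <- readLines(positions_path, n = 1)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- utils::read.csv(positions_path, header = has_header,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    gsi_validation_error("positions file must have >= 6 columns, got ", ncol(df))
  names(df)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                      "pixel_row", "pixel_col")
  if (anyDuplicated(df$barcode))
    gsi_validation_error("duplicate barcodes in positions file: ",
                         paste(unique(df$barcode[duplicated(df$barcode)]), collapse = ", "))
  df
}

#' Read a 10x-style Visium sample from a matrix directory
#'
#' Reads a `filtered_feature_bc_matrix`-style directory (Matrix-Market
#' triplet plus features/barcodes TSVs, optionally gzipped) together with a
#' `tissue_positions` table, keeping only spots flagged in-tissue. Spot order
#' follows the barcode file.
#'
#' @param dir_path Directory containing `matrix.mtx`, `features.tsv` (or
#'   `genes.tsv`), `barcodes.tsv`, each optionally `.gz`.
#' @param positions_path Path to the `tissue_positions` CSV (legacy
#'   headerless 6-column or headered dialect).
#' @param sample_id Sample identifier; defaults to the directory name.
#' @return An [st_sample()] with counts populated and `M` empty.
#' @export
read_visium <- function(dir_path, positions_path,
                        sample_id = basename(normalizePath(dir_path))) {
  if (!dir.exists(dir_path)) gsi_io_error("missing directory: ", dir_path)
  mtx_path <- find_mtx_file(dir_path, "matrix.mtx")
  feat_path <- find_mtx_file(dir_path, c("features.tsv", "genes.tsv"))
  bc_path <- find_mtx_file(dir_path, "barcodes.tsv")

  counts <- Matrix::readMM(mtx_path)
  feats <- read_tsv_nohead(feat_path)
  barcodes <- read_tsv_nohead(bc_path)[[1]]
  gene_ids <- feats[[1]]
  gene_symbols <- if (ncol(feats) >= 2) feats[[2]] else NULL
  if (nrow(counts) != length(gene_ids))
    gsi_validation_error("matrix rows (", nrow(counts), ") != features (",
                         length(gene_ids), ")")
  if (ncol(counts) != length(barcodes))
    gsi_validation_error("matrix cols (", ncol(counts), ") != barcodes (",
                         length(barcodes), ")")

  pos <- read_positions(positions_path)
  absent <- setdiff(barcodes, pos$barcode)
  if (length(absent))
    gsi_validation_error("barcodes absent from positions file: ",
                         paste(head(absent, 10), collapse = ", "))
  pos <- pos[match(barcodes, pos$barcode), , drop = FALSE]
  keep <- pos$in_tissue == 1
  coords <- data.frame(barcode = pos$barcode[keep],
                       array_row = as.integer(pos$array_row[keep]),
                       array_col = as.integer(pos$array_col[keep]),
                       pixel_row = pos$pixel_row[keep],
                       pixel_col = pos$pixel_col[keep],
                       stringsAsFactors = FALSE)
  st_sample(sample_id = sample_id,
            counts = counts[, keep, drop = FALSE],
            gene_ids = gene_ids, barcodes = barcodes[keep], coords = coords,
            gene_symbols = gene_symbols)
}

#' Write a sample as a 10x-style matrix directory
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and a headered
#' `tissue_positions.csv` (all uncompressed), the layout [read_visium()]
#' consumes. Raw counts are written; the normalized matrix is not.
#'
#' @param s An [st_sample()].
#' @param dir_path Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_visium <- function(s, dir_path) {
  stopifnot(inherits(s, "STSample"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(s$counts, file.path(dir_path, "matrix.mtx"))
  sym <- if (is.null(s$gene_symbols)) s$gene_ids else s$gene_symbols
  write.table(data.frame(s$gene_ids, sym, "Gene Expression"),
              file.path(dir_path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(s$barcodes, file.path(dir_path, "barcodes.tsv"))
  pos <- data.frame(barcode = s$coords$barcode, in_tissue = 1L,
                    array_row = s$coords$array_row,
                    array_col = s$coords$array_col,
                    pxl_row_in_fullres = if ("pixel_row" %in% names(s$coords))
                      s$coords$pixel_row else s$coords$array_row,
                    pxl_col_in_fullres = if ("pixel_col" %in% names(s$coords))
                      s$coords$pixel_col else s$coords$array_col)
  utils::write.csv(pos, file.path(dir_path, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir_path)
}

#' Read per-spot region annotations
#'
#' @param s An [st_sample()].
#' @param path TSV with two columns: barcode, label (no header required;
#'   a header line starting with "barcode" is skipped).
#' @return The sample with `region_labels` populated (NA for unannotated
#'   spots).
#' @export
read_annotations <- function(s, path) {
  if (!file.exists(path)) gsi_io_error("missing file: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) == "barcode") df <- df[-1, , drop = FALSE]
  labels <- rep(NA_character_, length(s$barcodes))
  names(labels) <- s$barcodes
  hit <- df[[1]] %in% s$barcodes
  labels[df[[1]][hit]] <- df[[2]][hit]
  s$region_labels <- labels
  s
}

subset_spots <- function(s, keep) {
  s$counts <- s$counts[, keep, drop = FALSE]
  if (!is.null(s$M)) s$M <- s$M[, keep, drop = FALSE]
  s$barcodes <- s$barcodes[keep]
  s$coords <- s$coords[keep, , drop = FALSE]
  rownames(s$coords) <- NULL
  if (!is.null(s$region_labels)) s$region_labels <- s$region_labels[keep]
  s
}

#' Remove spots with zero total count
#'
#' Drops every spot whose column sum is zero; gene set and surviving spot
#' order are unchanged. Idempotent.
#'
#' @param s An [st_sample()] with counts populated.
#' @param min_spots_per_gene Optional gene filter: genes expressed in fewer
#'   spots are dropped. Defaults to 0 (off) -- only spots are filtered.
#' @return The filtered sample.
#' @export
filter_spots <- function(s, min_spots_per_gene = 0) {
  stopifnot(inherits(s, "STSample"))
  keep <- Matrix::colSums(s$counts) > 0
  if (!any(keep)) gsi_stop("empty sample after filtering")
  s <- subset_spots(s, keep)
  if (min_spots_per_gene > 0) {
    gkeep <- Matrix::rowSums(s$counts > 0) >= min_spots_per_gene
    if (!any(gkeep)) gsi_stop("no genes left after gene filtering")
    s$counts <- s$counts[gkeep, , drop = FALSE]
    if (!is.null(s$M)) s$M <- s$M[gkeep, , drop = FALSE]
    s$gene_ids <- s$gene_ids[gkeep]
    if (!is.null(s$gene_symbols)) s$gene_symbols <- s$gene_symbols[gkeep]
  }
  s
}

#' Log-normalize counts (Seurat LogNormalize convention)
#'
#' Sets `m_ij = ln(1 + counts_ij / colsum_j * scale_factor)`. Zeros are
#' preserved exactly. Refuses to run twice on the same sample.
#'
#' @param s An [st_sample()], already spot-filtered.
#' @param scale_factor Positive scale constant, default 10000.
#' @return The sample with `M` populated.
#' @export
lognormalize <- function(s, scale_factor = 10000) {
  stopifnot(inherits(s, "STSample"), scale_factor > 0)
  if (!is.null(s$M))
    gsi_stop("sample is already log-normalized; refusing to renormalize")
  cs <- Matrix::colSums(s$counts)
  if (any(cs == 0))
    gsi_stop("zero column sum; run filter_spots() first")
  M <- s$counts
  # operate on the sparse slots so zeros stay structural
  col_of <- rep(seq_len(ncol(M)), diff(M@p))
  M@x <- log1p(M@x / cs[col_of] * scale_factor)
  s$M <- M
  s
}

#' Restrict samples to a shared gene set and order
#'
#' Intersects gene IDs across samples and reorders every sample to the
#' shared lexicographic gene order, as required before row-wise stacking.
#'
#' @param samples List of [st_sample()] objects.
#' @return List of samples over the common genes, identical order.
#' @export
align_genes <- function(samples) {
  stopifnot(length(samples) >= 1)
  shared <- Reduce(intersect, lapply(samples, function(s) s$gene_ids))
  if (length(shared) == 0) gsi_stop("empty gene intersection across samples")
  shared <- sort(shared, method = "radix")
  lapply(samples, function(s) {
    idx <- match(shared, s$gene_ids)
    s$counts <- s$counts[idx, , drop = FALSE]
    if (!is.null(s$M)) s$M <- s$M[idx, , drop = FALSE]
    if (!is.null(s$gene_symbols)) s$gene_symbols <- s$gene_symbols[idx]
    s$gene_ids <- shared
    s
  })
}
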