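#' Rasterize one gene's spatial distribution to a fixed-size binary image
#'
#' Builds the native occupancy grid over the Visium array coordinates --
#' cell (r, c) is 1 iff some spot at that position has positive normalized
#' expression -- then resamples it to `target` with nearest-neighbour
#' index mapping `src = floor((dst + 0.5) * src_extent / dst_extent)`.
#' The center-aligned floor rule is spelled out (rather than delegated to an
#' image library) so output is bit-identical across platforms. Overlapping
#' spots in one grid cell simply OR together.
#'
#' @param m_row Numeric vector of normalized expression over spots.
#' @param coords Data frame (or 2-column matrix) of non-negative integer
#'   `array_row`, `array_col` per spot.
#' @param target Integer pair (rows, cols) of the output raster,
#'   default c(220, 280).
#' @return Binary integer matrix of dimension `target`.
#' @export
rasterize_gene <- function(m_row, coords, target = c(220L, 280L)) {
  if (is.data.frame(coords)) {
    coords <- cbind(coords$array_row, coords$array_col)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) gsi_stop("empty coordinates")
  if (length(m_row) != nrow(coords))
    gsi_stop("length(m_row) != number of coordinate rows")
  if (any(coords < 0)) gsi_stop("negative array coordinates")
  storage.mode(coords) <- "integer"

  nr <- max(coords[, 1]) + 1L
  nc <- max(coords[, 2]) + 1L
  grid <- matrix(0L, nr, nc)
  on_idx <- m_row > 0
  if (any(on_idx)) {
    grid[cbind(coords[on_idx, 1] + 1L, coords[on_idx, 2] + 1L)] <- 1L
  }
  resize_nn(grid, target[1], target[2])
}

# Nearest-neighbour resize with the center-aligned floor mapping.
resize_nn <- function(grid, t_rows, t_cols) {
  src_r <- floor((seq_len(t_rows) - 0.5) * nrow(grid) / t_rows) + 1L
  src_c <- floor((seq_len(t_cols) - 0.5) * ncol(grid) / t_cols) + 1L
  grid[src_r, src_c, drop = FALSE]
}

#' Rasterize every gene of a sample into an image stack
#'
#' @param s A log-normalized [st_sample()].
#' @param target Raster dimensions (rows, cols), default c(220, 280).
#' @param intensity If `TRUE`, pixels carry the normalized expression value
#'   instead of being binarized (off by default; the canonical
#'   representation is binary presence/absence).
#' @return A `GeneImageStack`: list with `images` (3D array
#'   N_gene x rows x cols), `gene_ids`, `sample_id`, `height`, `width`.
#' @export
rasterize_sample <- function(s, target = c(220L, 280L), intensity = FALSE) {
  stopifnot(inherits(s, "STSample"))
  if (is.null(s$M)) gsi_stop("sample not normalized; run lognormalize() first")
  n_gene <- nrow(s$M)
  imgs <- array(0, dim = c(n_gene, target[1], target[2]))
  coords <- cbind(s$coords$array_row, s$coords$array_col)
  M <- as.matrix(s$M)
  for (i in seq_len(n_gene)) {
    img <- rasterize_gene(M[i, ], coords, target)
    if (intensity) {
      # value raster: paint each occupied native cell with the max m over
      # its spots, then apply the same NN resize
      nr <- max(coords[, 1]) + 1L; nc <- max(coords[, 2]) + 1L
      g <- matrix(0, nr, nc)
      for (j in which(M[i, ] > 0)) {
        r <- coords[j, 1] + 1L; c <- coords[j, 2] + 1L
        g[r, c] <- max(g[r, c], M[i, j])
      }
      img <- resize_nn(g, target[1], target[2])
    }
    imgs[i, , ] <- img
  }
  structure(list(images = imgs, gene_ids = s$gene_ids,
                 sample_id = s$sample_id,
                 height = as.integer(target[1]), width = as.integer(target[2])),
            class = "GeneImageStack")
}

#' @export
print.GeneImageStack <- function(x, ...) {
  cat("GeneImageStack", x$sample_id, ":", dim(x$images)[1], "genes,",
      x$height, "x", x$width, "raster\n")
  invisible(x)
}
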