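#' Shared-nearest-neighbour graph of embedding columns
#'
#' kNN by Euclidean distance (each point's neighbour set includes itself),
#' edge weight = Jaccard overlap of neighbour sets, edges with weight below
#' `prune` dropped -- the Seurat-style SNN construction.
#'
#' @param embedding Numeric matrix, one row per column/spot, one column per
#'   latent dimension.
#' @param k_neighbors Neighbourhood size, default 20.
#' @param prune Jaccard pruning cutoff, default 1/15.
#' @return An undirected weighted `igraph` graph with one vertex per row.
#' @export
knn_graph <- function(embedding, k_neighbors = 20L, prune = 1 / 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < k_neighbors + 1)
    gsi_stop("need at least k_neighbors + 1 = ", k_neighbors + 1,
             " columns, got ", n)
  k <- min(k_neighbors, n - 1L)
  nn <- knn_index(embedding, k)
  # binary membership matrix: row i marks i's neighbour set (self included)
  ii <- rep(seq_len(n), k + 1L)
  jj <- c(as.integer(nn), seq_len(n))
  N <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(N)
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j
  i1 <- shared@i[keep] + 1L
  j1 <- shared@j[keep] + 1L
  cnt <- shared@x[keep]
  w <- cnt / (2 * (k + 1) - cnt)
  ok <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i1[ok], to = j1[ok], weight = w[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  g
}

#' Louvain community detection at a given resolution
#'
#' Thin, seeded wrapper around modularity-based Louvain clustering. Labels
#' are re-indexed to be contiguous from 0.
#'
#' @param graph An `igraph` graph (output of [knn_graph()]).
#' @param resolution Modularity resolution parameter.
#' @param seed Integer seed (node-order shuffling inside Louvain draws from
#'   R's RNG).
#' @return Integer vector of cluster ids, 0-based.
#' @export
louvain <- function(graph, resolution = 1, seed = 1L) {
  if (igraph::vcount(graph) == 0) gsi_stop("empty graph")
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_louvain(graph, resolution = resolution)))
  as.integer(factor(memb, levels = unique(memb))) - 1L
}

#' Grid search over Louvain resolutions
#'
#' Runs Louvain at every grid resolution on one SNN graph and selects the
#' labelling that best matches the target: if `truth_or_k` is a label vector
#' the selection maximizes ARI over annotated real-spot columns (the
#' truth-guided tuning protocol); if it is a single integer k, the
#' resolution whose cluster count is closest to k wins. Ties break toward
#' the lower resolution. Embedding pseudo-columns participate in the graph
#' and the clustering but are stripped from the reported labels.
#'
#' @param embedding Column x dim matrix (all columns, including any
#'   embedding pseudo-columns).
#' @param truth_or_k Character/factor truth labels per column (`NA` for
#'   unannotated or pseudo-columns), or a single integer target cluster
#'   count.
#' @param grid Resolutions to scan, default `seq(0.05, 2, by = 0.05)`.
#' @param seed Integer seed.
#' @param k_neighbors SNN neighbourhood size.
#' @param roles Optional per-column role vector; labels are reported only
#'   for `role == "spot"` columns (all columns if omitted).
#' @return A `ClusterResult`: list with `labels` (spot columns only),
#'   `all_labels`, `resolution`, `n_clusters`, `search_trace`.
#' @export
resolution_search <- function(embedding, truth_or_k,
                              grid = seq(0.05, 2, by = 0.05), seed = 1L,
                              k_neighbors = 20L, roles = NULL) {
  if (length(grid) == 0) gsi_stop("empty resolution grid")
  grid <- sort(grid)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (is.null(roles)) roles <- rep("spot", n)
  spot_idx <- which(roles == "spot")
  by_truth <- length(truth_or_k) > 1 || !is.numeric(truth_or_k)
  if (by_truth) {
    truth <- as.character(truth_or_k)
    if (length(truth) == length(spot_idx) && length(truth) != n) {
      full <- rep(NA_character_, n)
      full[spot_idx] <- truth
      truth <- full
    }
    eval_idx <- which(!is.na(truth) & roles == "spot")
    if (length(eval_idx) < 2) gsi_stop("need >= 2 annotated spots for ARI tuning")
  } else {
    target_k <- as.integer(truth_or_k)
  }

  g <- knn_graph(embedding, k_neighbors = k_neighbors)
  trace <- data.frame(resolution = grid, n_clusters = NA_integer_,
                      score = NA_real_)
  best <- NULL
  for (i in seq_along(grid)) {
    lab <- louvain(g, resolution = grid[i], seed = seed)
    ncl <- length(unique(lab[spot_idx]))
    score <- if (by_truth) {
      ari(lab[eval_idx], truth[eval_idx])
    } else {
      -abs(ncl - target_k)
    }
    trace$n_clusters[i] <- ncl
    trace$score[i] <- score
    if (is.null(best) || score > best$score + 1e-12) {
      best <- list(labels = lab, resolution = grid[i], score = score)
    }
  }
  spot_labels <- best$labels[spot_idx]
  spot_labels <- as.integer(factor(spot_labels, levels = unique(spot_labels))) - 1L
  structure(list(labels = spot_labels, all_labels = best$labels,
                 resolution = best$resolution,
                 n_clusters = length(unique(spot_labels)),
                 score = best$score, search_trace = trace),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", x$n_clusters, "clusters at resolution", x$resolution,
      sprintf("(selection score %.4f)\n", x$score))
  invisible(x)
}
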