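#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions, from
#' the pair-count contingency table. 1 = identical partitions, ~0 = chance.
#'
#' @param labels_a,labels_b Label vectors of equal length (any atomic type).
#' @return ARI in \[-0.5, 1\].
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    gsi_stop("label vectors differ in length")
  if (length(labels_a) < 2) gsi_stop("need >= 2 observations")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_comb - expected) / (max_index - expected)
}

entropy_counts <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

#' Normalized mutual information (arithmetic normalization)
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return NMI in \[0, 1\]; two single-cluster partitions score 1.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    gsi_stop("label vectors differ in length")
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  ha <- entropy_counts(rowSums(tab))
  hb <- entropy_counts(colSums(tab))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  p <- tab / n
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  }
  as.numeric(mi / ((ha + hb) / 2))
}

#' Per-point silhouette widths
#'
#' Euclidean silhouette computed blockwise (no full distance matrix held).
#' Points in singleton clusters get width 0.
#'
#' @param embedding Numeric matrix, one row per point.
#' @param labels Cluster labels per row (>= 2 distinct).
#' @return Numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_widths <- function(embedding, labels) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  n <- nrow(embedding)
  lev <- unique(labels)
  if (length(lev) < 2) gsi_stop("silhouette needs >= 2 distinct labels")
  grp <- match(labels, lev)
  sizes <- tabulate(grp, nbins = length(lev))
  s <- numeric(n)
  sq <- rowSums(embedding^2)
  block <- 1024L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") -
      2 * tcrossprod(embedding[idx, , drop = FALSE], embedding)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    # sum of distances from each point in the block to every label group
    sums <- t(rowsum(t(d), grp))           # |idx| x n_lev
    for (r in seq_along(idx)) {
      i <- idx[r]
      gi <- grp[i]
      if (sizes[gi] <= 1) { s[i] <- 0; next }
      a_i <- sums[r, gi] / (sizes[gi] - 1)
      b_i <- min(sums[r, -gi] / sizes[-gi])
      s[i] <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
    }
  }
  s
}

#' Average silhouette width rescaled to \[0, 1\]
#'
#' @param embedding Numeric matrix of points.
#' @param labels Grouping labels.
#' @return `mean((s + 1) / 2)`, or `NA` with a single label.
#' @export
asw <- function(embedding, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  mean((silhouette_widths(embedding, labels) + 1) / 2)
}

#' Local inverse-Simpson index (LISI)
#'
#' Per point, a Gaussian kernel over its `3 * perplexity` nearest
#' neighbours is calibrated by binary search so the kernel entropy matches
#' `log(perplexity)`; the inverse Simpson index of the kernel-weighted
#' label distribution is the point's effective number of distinct labels in
#' its neighbourhood.
#'
#' @param embedding Numeric matrix of points.
#' @param labels Label vector (batch labels for iLISI, class labels for
#'   cLISI).
#' @param perplexity Neighbourhood scale, default 30.
#' @param nn Optional precomputed neighbour-index matrix (n x >= 3*perplexity)
#'   to avoid recomputing kNN.
#' @return Numeric vector of per-point scores in \[1, #labels\].
#' @export
lisi <- function(embedding, labels, perplexity = 30, nn = NULL) {
  embedding <- as.matrix(embedding)
  labels <- as.character(labels)
  n <- nrow(embedding)
  lev <- unique(labels)
  if (length(lev) < 2) return(rep(1, n))
  k <- min(as.integer(3 * perplexity), n - 1L)
  perplexity <- min(perplexity, k / 1.05)
  if (is.null(nn)) nn <- knn_index(embedding, k)
  else nn <- nn[, seq_len(min(k, ncol(nn))), drop = FALSE]
  k <- ncol(nn)
  grp <- match(labels, lev)
  log_u <- log(perplexity)
  # squared distances to each point's k neighbours (n x k)
  sq <- rowSums(embedding^2)
  d2 <- matrix(sq[as.integer(nn)], n, k) + sq -
    2 * t(vapply(seq_len(n), function(i)
      as.numeric(embedding[nn[i, ], , drop = FALSE] %*% embedding[i, ]),
      numeric(k)))
  d2[d2 < 0] <- 0
  # vectorized binary search for the per-point kernel precision beta
  beta <- rep(1, n)
  lo <- rep(-Inf, n); hi <- rep(Inf, n)
  for (iter in 1:50) {
    w <- exp(-d2 * beta)
    sw <- rowSums(w)
    p <- w / pmax(sw, .Machine$double.xmin)
    plog <- p * log(pmax(p, .Machine$double.xmin))
    h <- -rowSums(plog)
    h[sw == 0] <- 0
    diff <- h - log_u
    up <- diff > 0
    lo[up] <- beta[up]
    hi[!up] <- beta[!up]
    beta <- ifelse(up,
                   ifelse(is.finite(hi), (beta + hi) / 2, beta * 2),
                   ifelse(is.finite(lo), (beta + lo) / 2, beta / 2))
    if (max(abs(diff)) < 1e-5) break
  }
  w <- exp(-d2 * beta)
  sw <- rowSums(w)
  p <- w / pmax(sw, .Machine$double.xmin)
  out <- numeric(n)
  nn_grp <- matrix(grp[as.integer(nn)], n, k)
  for (g in seq_along(lev)) {
    pg <- rowSums(p * (nn_grp == g))
    out <- out + pg^2
  }
  res <- 1 / out
  res[sw == 0] <- 1
  res
}

#' kBET-style local batch-composition test
#'
#' For each point, a chi-squared goodness-of-fit statistic compares the
#' batch composition of its `k0`-neighbourhood (self included) with the
#' global batch frequencies; the acceptance rate is the fraction of
#' neighbourhoods whose test is NOT rejected at level `alpha`.
#'
#' @param embedding Numeric matrix of points.
#' @param batch_labels Batch label per point (>= 2 batches).
#' @param k0 Neighbourhood size, default 50.
#' @param alpha Significance level, default 0.05.
#' @param nn Optional precomputed neighbour-index matrix (n x >= k0).
#' @return List with `acceptance` (scalar), `rejection`, `pvalues`.
#' @export
kbet <- function(embedding, batch_labels, k0 = 50L, alpha = 0.05, nn = NULL) {
  embedding <- as.matrix(embedding)
  batch <- as.character(batch_labels)
  lev <- unique(batch)
  if (length(lev) < 2) gsi_stop("kBET needs >= 2 batches")
  n <- nrow(embedding)
  k0 <- min(as.integer(k0), n - 1L)
  if (is.null(nn)) nn <- knn_index(embedding, k0)
  else nn <- nn[, seq_len(k0), drop = FALSE]
  grp <- match(batch, lev)
  glob <- tabulate(grp, nbins = length(lev)) / n
  expd <- (k0 + 1) * glob
  nbhd <- cbind(seq_len(n), nn)                 # self included
  nb_grp <- matrix(grp[as.integer(nbhd)], n, k0 + 1L)
  stat <- numeric(n)
  for (g in seq_along(lev)) {
    obs_g <- rowSums(nb_grp == g)
    stat <- stat + (obs_g - expd[g])^2 / expd[g]
  }
  pv <- pchisq(stat, df = length(lev) - 1, lower.tail = FALSE)
  list(acceptance = mean(pv >= alpha), rejection = mean(pv < alpha),
       pvalues = pv)
}

#' Per-label kNN-graph connectivity
#'
#' For each ground-truth label, the fraction of its points lying in the
#' largest connected component of the label-restricted kNN graph; averaged
#' over labels. 1 means every label forms a single connected blob in the
#' embedding.
#'
#' @param embedding Numeric matrix of points.
#' @param truth_labels Ground-truth label per point.
#' @param k Neighbourhood size, default 15.
#' @return Scalar in (0, 1\].
#' @export
graph_connectivity <- function(embedding, truth_labels, k = 15L) {
  embedding <- as.matrix(embedding)
  truth <- as.character(truth_labels)
  vals <- vapply(unique(truth), function(l) {
    ix <- which(truth == l)
    if (length(ix) < 2) return(1)
    kk <- min(k, length(ix) - 1L)
    nn <- knn_index(embedding[ix, , drop = FALSE], kk)
    g <- igraph::graph_from_edgelist(
      cbind(rep(seq_along(ix), kk), as.integer(nn)), directed = FALSE)
    comp <- igraph::components(g)
    max(comp$csize) / length(ix)
  }, numeric(1))
  mean(vals)
}

# Per-point silhouette from precomputed distance sums to each label group.
sil_from_sums <- function(sums, sizes, grp) {
  n <- nrow(sums)
  a <- sums[cbind(seq_len(n), grp)] / pmax(sizes[grp] - 1, 1)
  b <- rep(Inf, n)
  for (g in seq_along(sizes)) {
    other <- grp != g
    b[other] <- pmin(b[other], sums[other, g] / sizes[g])
  }
  s <- ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  s[sizes[grp] <= 1] <- 0
  s
}

# Silhouette of the binary partition {group g, rest}, from the same sums.
sil_binary_from_sums <- function(sums, sizes, grp, g) {
  n <- nrow(sums)
  total <- rowSums(sums)
  sum_g <- sums[, g]
  n_g <- sizes[g]
  n_rest <- n - n_g
  if (n_g < 1 || n_rest < 1) return(rep(0, n))
  in_g <- grp == g
  a <- ifelse(in_g, sum_g / pmax(n_g - 1, 1), (total - sum_g) / pmax(n_rest - 1, 1))
  b <- ifelse(in_g, (total - sum_g) / n_rest, sum_g / n_g)
  s <- ifelse(pmax(a, b) == 0, 0, (b - a) / pmax(a, b))
  if (n_g == 1) s[in_g] <- 0
  if (n_rest == 1) s[!in_g] <- 0
  s
}

isolated_labels <- function(truth, batch) {
  tab <- table(truth, batch)
  n_batches <- rowSums(tab > 0)
  names(n_batches)[n_batches == min(n_batches)]
}

f1_score <- function(pred_bin, truth_bin) {
  tp <- sum(pred_bin & truth_bin)
  if (tp == 0) return(0)
  prec <- tp / sum(pred_bin)
  rec <- tp / sum(truth_bin)
  2 * prec * rec / (prec + rec)
}

#' Biological-conservation metric panel
#'
#' ARI and NMI of the clustering against ground truth; truth-label ASW on
#' the embedding (rescaled to \[0,1\]); cLISI rescaled so 1 = perfectly pure
#' neighbourhoods; isolated-label F1 and ASW (labels present in the fewest
#' batches). Only annotated points enter; pass pre-filtered inputs.
#'
#' @param embedding Numeric matrix (annotated real spots only).
#' @param cluster_labels Cluster assignment per point.
#' @param truth_labels Ground-truth label per point.
#' @param batch_labels Batch per point (needed for the isolated-label set).
#' @param lisi_perplexity Perplexity for cLISI, default 30.
#' @return Named list: `ari`, `nmi`, `asw_cell`, `clisi`, `iso_f1`,
#'   `iso_asw`.
#' @export
bio_conservation <- function(embedding, cluster_labels, truth_labels,
                             batch_labels, lisi_perplexity = 30, nn = NULL) {
  embedding <- as.matrix(embedding)
  truth <- as.character(truth_labels)
  lev <- unique(truth)
  n_lab <- length(lev)
  if (n_lab > 1) {
    grp <- match(truth, lev)
    ds <- label_dist_sums(embedding, grp, n_lab)
    asw_cell <- mean((sil_from_sums(ds$sums, ds$sizes, grp) + 1) / 2)
  } else {
    asw_cell <- NA_real_
  }
  cl <- lisi(embedding, truth, perplexity = lisi_perplexity, nn = nn)
  clisi <- if (n_lab > 1) mean((n_lab - cl) / (n_lab - 1)) else NA_real_
  iso <- isolated_labels(truth, batch_labels)
  iso_f1 <- mean(vapply(iso, function(l) {
    max(vapply(unique(cluster_labels), function(cc)
      f1_score(cluster_labels == cc, truth == l), numeric(1)))
  }, numeric(1)))
  iso_asw <- if (n_lab > 1) mean(vapply(iso, function(l) {
    mean((sil_binary_from_sums(ds$sums, ds$sizes, grp, match(l, lev)) + 1) / 2)
  }, numeric(1))) else NA_real_
  list(ari = ari(cluster_labels, truth),
       nmi = nmi(cluster_labels, truth),
       asw_cell = asw_cell, clisi = clisi,
       iso_f1 = iso_f1, iso_asw = iso_asw)
}

#' Batch-mixing metric panel
#'
#' Batch ASW (1 - |silhouette| by batch within each truth label, averaged),
#' per-label kNN-graph connectivity, iLISI (raw and rescaled to \[0,1\]),
#' and kBET acceptance.
#'
#' @param embedding Numeric matrix (annotated real spots only).
#' @param batch_labels Batch per point (>= 2 batches).
#' @param truth_labels Ground-truth label per point.
#' @param kbet_k0,lisi_perplexity,gc_k Neighbourhood sizes.
#' @return Named list: `batch_asw`, `graph_connectivity`, `ilisi_raw`,
#'   `ilisi`, `kbet_acceptance`.
#' @export
batch_mixing <- function(embedding, batch_labels, truth_labels,
                         kbet_k0 = 50L, lisi_perplexity = 30, gc_k = 15L,
                         nn = NULL) {
  batch <- as.character(batch_labels)
  truth <- as.character(truth_labels)
  n_batch <- length(unique(batch))
  if (n_batch < 2) gsi_stop("batch mixing needs >= 2 batches")
  vals <- c()
  for (l in unique(truth)) {
    ix <- which(truth == l)
    tab <- table(batch[ix])
    if (length(tab) < 2 || any(tab < 2)) {
      warning("label ", l, " skipped in batch ASW (batch with < 2 members)")
      next
    }
    s <- silhouette_widths(embedding[ix, , drop = FALSE], batch[ix])
    vals <- c(vals, mean(1 - abs(s)))
  }
  il <- lisi(embedding, batch, perplexity = lisi_perplexity, nn = nn)
  k0 <- min(as.integer(kbet_k0), nrow(as.matrix(embedding)) - 1L)
  kb_nn <- if (!is.null(nn) && ncol(nn) >= k0) nn else NULL
  list(batch_asw = if (length(vals)) mean(vals) else NA_real_,
       graph_connectivity = graph_connectivity(embedding, truth, k = gc_k),
       ilisi_raw = mean(il),
       ilisi = mean((il - 1) / (n_batch - 1)),
       kbet_acceptance = kbet(embedding, batch, k0 = kbet_k0,
                              nn = kb_nn)$acceptance)
}

#' Full integration metric report
#'
#' Combines [bio_conservation()] and [batch_mixing()] on the annotated
#' real-spot columns of an embedding.
#'
#' @param embedding Column x dim matrix.
#' @param cluster_labels,truth_labels,batch_labels Per-column vectors
#'   (`NA` truth = unannotated, excluded).
#' @param ... Neighbourhood-size overrides passed through.
#' @return A `MetricReport` list with both panels plus `n_cells`,
#'   `n_batches`, `n_labels`.
#' @export
metric_report <- function(embedding, cluster_labels, truth_labels,
                          batch_labels, ...) {
  keep <- !is.na(truth_labels)
  emb <- as.matrix(embedding)[keep, , drop = FALSE]
  cl <- cluster_labels[keep]
  tr <- truth_labels[keep]
  ba <- batch_labels[keep]
  # one shared kNN serves cLISI, iLISI and kBET
  k_shared <- min(max(90L, 50L), nrow(emb) - 1L)
  nn <- knn_index(emb, k_shared)
  bio <- bio_conservation(emb, cl, tr, ba, nn = nn)
  mix <- if (length(unique(ba)) >= 2) batch_mixing(emb, ba, tr, nn = nn, ...) else
    list(batch_asw = NA_real_, graph_connectivity = NA_real_,
         ilisi_raw = NA_real_, ilisi = NA_real_, kbet_acceptance = NA_real_)
  structure(c(bio, mix,
              list(n_cells = sum(keep), n_batches = length(unique(ba)),
                   n_labels = length(unique(tr)))),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat("MetricReport (", x$n_cells, "cells,", x$n_labels, "labels,",
      x$n_batches, "batches )\n")
  num <- vapply(x[c("ari", "nmi", "asw_cell", "clisi", "iso_f1", "iso_asw",
                    "batch_asw", "graph_connectivity", "ilisi",
                    "kbet_acceptance")], identity, numeric(1))
  print(round(num, 4))
  invisible(x)
}
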