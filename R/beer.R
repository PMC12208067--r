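#' Hyperparameters for batch-effect removal
#'
#' Defaults follow the published configuration: GNUM = 50 column groups per
#' batch, PCNUM = 30 principal components, ROUND = 2 refinement rounds,
#' GN = 1500 variable genes, SEED = 1, ComBat pre-correction on. The PC
#' retention cutoff (`cor_threshold`, Spearman by default) is an
#' implementation default exposed here because the original configuration
#' does not state one.
#'
#' @param GNUM Groups per batch for mutual-pair construction (>= 2).
#' @param PCNUM Number of PCs computed (>= 2).
#' @param ROUND Pairing/scoring refinement rounds.
#' @param GN Number of variable genes used for PCA (clipped to N_gene).
#' @param SEED Integer seed controlling grouping.
#' @param COMBAT Apply empirical-Bayes correction before PCA.
#' @param cor_threshold Minimum cross-batch pair correlation for a PC to be
#'   retained.
#' @param cor_method Correlation flavour, `"spearman"` or `"pearson"`.
#' @return A `BeerParams` list.
#' @export
beer_params <- function(GNUM = 50L, PCNUM = 30L, ROUND = 2L, GN = 1500L,
                        SEED = 1L, COMBAT = TRUE, cor_threshold = 0.7,
                        cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  if (GNUM < 2) gsi_stop("GNUM must be >= 2")
  if (PCNUM < 2) gsi_stop("PCNUM must be >= 2")
  if (cor_threshold <= 0 || cor_threshold >= 1)
    gsi_stop("cor_threshold must be in (0,1)")
  structure(list(GNUM = as.integer(GNUM), PCNUM = as.integer(PCNUM),
                 ROUND = as.integer(ROUND), GN = as.integer(GN),
                 SEED = as.integer(SEED), COMBAT = isTRUE(COMBAT),
                 cor_threshold = cor_threshold, cor_method = cor_method),
            class = "BeerParams")
}

#' Select highly variable genes by dispersion
#'
#' Ranks genes by variance-to-mean dispersion across columns and keeps the
#' top `GN` (clipped to the number of genes). Ties at the cutoff break
#' deterministically toward the lexicographically smaller gene ID.
#'
#' @param X Gene x column matrix with rownames.
#' @param GN Number of genes to keep.
#' @return Integer vector of row indices, in dispersion order.
#' @export
select_variable_genes <- function(X, GN) {
  if (GN < 1) gsi_stop("GN must be >= 1")
  X <- as.matrix(X)
  mu <- rowMeans(X)
  v <- apply(X, 1, var)
  disp <- ifelse(mu > 0, v / mu, v)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("g%08d", seq_len(nrow(X)))
  ord <- order(-disp, ids, method = "radix")
  ord[seq_len(min(GN, nrow(X)))]
}

# Seeded k-means grouping of one batch's columns in PC space.
group_batch <- function(scores, cols, GNUM, seed) {
  x <- scores[cols, , drop = FALSE]
  k <- min(GNUM, nrow(unique(x)))
  if (k < 2) return(list(rep(1L, length(cols))))
  km <- with_seed(seed, kmeans(x, centers = k, nstart = 10, iter.max = 50))
  split(seq_along(cols), km$cluster)
}

#' Build mutual cross-batch group pairs
#'
#' Columns of each batch are clustered into up to `GNUM` groups by seeded
#' k-means on the supplied PC scores; for every unordered batch pair, group
#' centroids are matched and a pair is kept iff each group is the other's
#' nearest foreign centroid (mutual nearest pairs).
#'
#' @param pc_scores Column x PC score matrix (possibly restricted to the
#'   currently retained PCs).
#' @param batch_labels Per-column batch labels (>= 2 batches).
#' @param GNUM Maximum groups per batch.
#' @param seed Integer seed.
#' @return List of pairs; each a list with `cols1`, `cols2` (column indices
#'   into `pc_scores`), `batch1`, `batch2`.
#' @export
group_and_pair <- function(pc_scores, batch_labels, GNUM = 50L, seed = 1L) {
  pc_scores <- as.matrix(pc_scores)
  batches <- unique(batch_labels)
  if (length(batches) < 2) gsi_stop("need >= 2 batches to pair")
  groups <- list()
  for (b in batches) {
    cols <- which(batch_labels == b)
    if (length(cols) < 2) gsi_stop("batch ", b, " has fewer than 2 columns")
    # one shared seed: identical batches then produce identical groupings
    memb <- group_batch(pc_scores, cols, GNUM, derive_seed(seed, "kmeans"))
    groups[[b]] <- lapply(memb, function(ix) cols[ix])
  }
  centroid <- function(ix) colMeans(pc_scores[ix, , drop = FALSE])
  cents <- lapply(groups, function(gl) t(vapply(gl, centroid,
                                                numeric(ncol(pc_scores)))))
  pairs <- list()
  for (i in seq_along(batches)) for (j in seq_along(batches)) {
    if (i >= j) next
    a <- batches[i]; b <- batches[j]
    d2 <- cross_dist2(cents[[a]], cents[[b]])
    nn_ab <- apply(d2, 1, which.min)
    nn_ba <- apply(d2, 2, which.min)
    for (g in seq_along(nn_ab)) {
      h <- nn_ab[g]
      if (nn_ba[h] == g) {
        pairs[[length(pairs) + 1]] <- list(cols1 = groups[[a]][[g]],
                                           cols2 = groups[[b]][[h]],
                                           batch1 = a, batch2 = b)
      }
    }
  }
  pairs
}

#' Score principal components by cross-batch pair correlation
#'
#' For each PC, correlates the paired group-centroid scores across the
#' mutual pairs. A low (or negative) correlation marks a component dominated
#' by batch effect rather than shared biology.
#'
#' @param pc_scores Column x PC score matrix (all PCs).
#' @param pairs Output of [group_and_pair()].
#' @param cor_method `"spearman"` or `"pearson"`.
#' @return Numeric vector, one correlation per PC (NA-free; degenerate
#'   constant scores score 0).
#' @export
score_pcs <- function(pc_scores, pairs, cor_method = "spearman") {
  pc_scores <- as.matrix(pc_scores)
  if (length(pairs) < 3)
    gsi_stop("need >= 3 mutual pairs to score PCs, got ", length(pairs))
  x <- vapply(pairs, function(p)
    colMeans(pc_scores[p$cols1, , drop = FALSE]), numeric(ncol(pc_scores)))
  y <- vapply(pairs, function(p)
    colMeans(pc_scores[p$cols2, , drop = FALSE]), numeric(ncol(pc_scores)))
  out <- vapply(seq_len(ncol(pc_scores)), function(k) {
    if (sd(x[k, ]) == 0 || sd(y[k, ]) == 0) return(0)
    cor(x[k, ], y[k, ], method = cor_method)
  }, numeric(1))
  out[!is.finite(out)] <- 0
  out
}

# Center+scale gene rows; zero-variance rows become zero.
scale_rows <- function(X) {
  mu <- rowMeans(X)
  s <- apply(X, 1, sd)
  s[s == 0] <- 1
  (X - mu) / s
}

# PCA over columns (columns = observations, genes = features), deterministic
# sign: the largest-|loading| entry of each component is made positive.
pca_columns <- function(S, npc) {
  p <- prcomp(t(S), center = FALSE, scale. = FALSE, rank. = npc)
  npc <- min(npc, ncol(p$x))
  scores <- p$x[, seq_len(npc), drop = FALSE]
  rot <- p$rotation[, seq_len(npc), drop = FALSE]
  for (k in seq_len(npc)) {
    i <- which.max(abs(rot[, k]))
    if (rot[i, k] < 0) {
      rot[, k] <- -rot[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, rotation = rot, sdev = p$sdev[seq_len(npc)])
}

#' Batch-effect removal by PC rejection with mutual cross-batch pairs
#'
#' Pipeline: optional empirical-Bayes correction of the full integrated
#' matrix; restriction to `GN` variable genes, per-gene centering/scaling;
#' PCA to `PCNUM` components over columns; seeded grouping and mutual
#' cross-batch pairing; per-PC pair correlation; PCs whose correlation falls
#' below `cor_threshold` are rejected as batch-driven. Pairing/scoring is
#' repeated `ROUND` times, re-pairing on the currently retained PCs. At
#' least two PCs are always retained.
#'
#' With a single batch the procedure degrades gracefully: no correction,
#' every PC retained, the embedding is plain PCA.
#'
#' @param im An `IntegratedMatrix` (or plain gene x column matrix, in which
#'   case `batch_labels` must be given).
#' @param params A [beer_params()] object.
#' @param batch_labels Optional per-column batch labels when `im` is a bare
#'   matrix.
#' @return A `CorrectedResult`: list with `C_prime` (corrected full
#'   matrix), `pc_scores` (column x PCNUM), `retained_pcs`,
#'   `pc_correlations`, `embedding` (scores restricted to retained PCs),
#'   `rounds` (per-round retained sets), `params`.
#' @export
beer <- function(im, params = beer_params(), batch_labels = NULL) {
  if (inherits(im, "IntegratedMatrix")) {
    X <- im$C
    batch_labels <- im$batch_labels
  } else {
    X <- as.matrix(im)
    if (is.null(batch_labels)) gsi_stop("batch_labels required for bare matrix")
  }
  stopifnot(inherits(params, "BeerParams"))
  n_batches <- length(unique(batch_labels))

  Xc <- if (params$COMBAT && n_batches >= 2) combat(X, batch_labels) else X

  vg <- select_variable_genes(X, params$GN)
  S <- scale_rows(Xc[vg, , drop = FALSE])
  npc <- min(params$PCNUM, ncol(S) - 1L, nrow(S))
  pca <- pca_columns(S, npc)
  scores <- pca$scores

  retained <- seq_len(npc)
  cors <- rep(NA_real_, npc)
  rounds_log <- list()
  if (n_batches >= 2) {
    min_batch <- min(table(batch_labels))
    for (r in seq_len(params$ROUND)) {
      # mutual pairing can come up short when batches are far apart (the
      # nearest-foreign map collapses onto few centroids); refine the
      # grouping until >= 3 mutual pairs exist or groups cannot get finer
      gnum_eff <- params$GNUM
      repeat {
        pairs <- group_and_pair(scores[, retained, drop = FALSE],
                                batch_labels, GNUM = gnum_eff,
                                seed = derive_seed(params$SEED,
                                                   paste0("round", r)))
        if (length(pairs) >= 3 || gnum_eff >= min_batch %/% 2) break
        gnum_eff <- min(gnum_eff * 2L, min_batch %/% 2)
      }
      if (length(pairs) < 3) {
        if (r == 1) gsi_stop("need >= 3 mutual pairs to score PCs, got ",
                             length(pairs))
        # a refinement round that cannot form enough pairs (degenerate
        # low-dimensional retained space) keeps the previous round's result
        break
      }
      cors <- score_pcs(scores, pairs, params$cor_method)
      retained <- which(cors >= params$cor_threshold)
      if (length(retained) < 2)
        retained <- order(cors, decreasing = TRUE)[1:2]
      retained <- sort(retained)
      rounds_log[[r]] <- retained
    }
  } else {
    cors <- rep(1, npc)
    rounds_log[[1]] <- retained
  }

  structure(list(C_prime = Xc, pc_scores = scores,
                 retained_pcs = retained, pc_correlations = cors,
                 embedding = scores[, retained, drop = FALSE],
                 rounds = rounds_log, variable_genes = vg,
                 batch_labels = batch_labels, params = params),
            class = "CorrectedResult")
}

#' @export
print.CorrectedResult <- function(x, ...) {
  cat("CorrectedResult:", nrow(x$C_prime), "genes x", ncol(x$C_prime),
      "columns;", length(x$retained_pcs), "of", ncol(x$pc_scores),
      "PCs retained:", paste(x$retained_pcs, collapse = " "), "\n")
  invisible(x)
}
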