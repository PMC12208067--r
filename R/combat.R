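#' Empirical-Bayes batch correction (parametric ComBat)
#'
#' Per-gene location/scale batch adjustment: genes are standardized against
#' the pooled mean/variance, per-batch additive and multiplicative effects
#' are estimated and shrunk toward their batch-wide priors (normal prior on
#' additive effects, inverse-gamma on multiplicative), then removed and the
#' data back-transformed. Batch-only design, parametric priors.
#'
#' Genes with zero pooled variance are returned unchanged; a single batch is
#' an identity operation.
#'
#' @param X Gene x column numeric matrix.
#' @param batch_labels Per-column batch factor/character vector.
#' @param conv Convergence tolerance of the EB fixed-point iteration.
#' @return Corrected matrix, same shape and dimnames as `X`.
#' @export
combat <- function(X, batch_labels, conv = 1e-4) {
  X <- as.matrix(X)
  batch <- as.factor(batch_labels)
  if (length(batch) != ncol(X))
    gsi_stop("batch_labels length != ncol(X)")
  if (nlevels(batch) < 2) return(X)
  n_per <- table(batch)
  if (any(n_per < 2))
    gsi_stop("every batch needs >= 2 columns; offending: ",
             paste(names(n_per)[n_per < 2], collapse = ", "))

  n_array <- ncol(X)
  batches <- levels(batch)
  idx_b <- lapply(batches, function(b) which(batch == b))

  # batch means per gene and pooled variance about them
  B_hat <- vapply(idx_b, function(ix) rowMeans(X[, ix, drop = FALSE]),
                  numeric(nrow(X)))                       # gene x batch
  w <- as.numeric(n_per[batches]) / n_array
  grand_mean <- as.numeric(B_hat %*% w)
  fitted <- B_hat[, as.integer(batch), drop = FALSE]
  var_pooled <- rowSums((X - fitted)^2) / n_array

  ok <- var_pooled > 0
  if (!any(ok)) return(X)
  Xo <- X[ok, , drop = FALSE]
  gm <- grand_mean[ok]
  vp <- var_pooled[ok]

  Z <- (Xo - gm) / sqrt(vp)

  gamma_hat <- vapply(idx_b, function(ix) rowMeans(Z[, ix, drop = FALSE]),
                      numeric(nrow(Z)))
  delta_hat <- vapply(seq_along(idx_b), function(j) {
    ix <- idx_b[[j]]
    rowSums((Z[, ix, drop = FALSE] - gamma_hat[, j])^2) / (length(ix) - 1)
  }, numeric(nrow(Z)))

  aprior <- function(d) { m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2 }
  bprior <- function(d) { m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2 }

  Z_adj <- Z
  for (j in seq_along(idx_b)) {
    ix <- idx_b[[j]]
    n_b <- length(ix)
    g_hat <- gamma_hat[, j]
    d_hat <- delta_hat[, j]
    g_bar <- mean(g_hat)
    t2 <- var(g_hat)
    a_pr <- aprior(d_hat)
    b_pr <- bprior(d_hat)
    # EB fixed point (parametric): shrink additive and multiplicative effects
    g_old <- g_hat
    d_old <- d_hat
    change <- 1
    iter <- 0
    Zb <- Z[, ix, drop = FALSE]
    while (change > conv && iter < 100) {
      g_new <- (t2 * n_b * g_hat + d_old * g_bar) / (t2 * n_b + d_old)
      sum2 <- rowSums((Zb - g_new)^2)
      d_new <- (0.5 * sum2 + b_pr) / (n_b / 2 + a_pr - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new
      d_old <- d_new
      iter <- iter + 1
    }
    Z_adj[, ix] <- (Zb - g_old) / sqrt(pmax(d_old, 1e-12))
  }

  out <- X
  out[ok, ] <- Z_adj * sqrt(vp) + gm
  out
}
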