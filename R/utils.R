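#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor kmeans prcomp pchisq rnorm rnbinom rbinom runif var sd
#' @importFrom utils read.delim write.csv head
NULL

# Abort helpers: consistent condition classes so callers/tests can match on them.
gsi_stop <- function(..., class = "gsi_error") {
  stop(errorCondition(paste0(...), class = c(class, "gsi_error")))
}

gsi_io_error <- function(...) gsi_stop(..., class = "gsi_io_error")
gsi_validation_error <- function(...) gsi_stop(..., class = "gsi_validation_error")

# Derive a child seed from a parent seed and a stage tag. Kept below 2^31-1.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L + 1)
}

# Run an expression under a local RNG state so library code does not disturb
# the caller's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Pairwise squared Euclidean distances between rows of a and rows of b,
# computed blockwise with BLAS. Returns a (nrow(a) x nrow(b)) dense matrix.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# k nearest neighbours among rows of x (self excluded), blockwise.
# Returns an n x k integer matrix of neighbour indices ordered by distance.
knn_index <- function(x, k, block = 1024L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) gsi_stop("k (", k, ") must be < number of rows (", n, ")")
  out <- matrix(0L, n, k)
  sq <- rowSums(x^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- -2 * tcrossprod(x[idx, , drop = FALSE], x)
    d2 <- d2 + rep(sq, each = length(idx))
    for (r in seq_along(idx)) {
      row <- d2[r, ] + sq[idx[r]]
      row[idx[r]] <- Inf
      # partial sort to the k-th smallest, then order only the candidates
      thr <- sort.int(row, partial = k)[k]
      cand <- which(row <= thr)
      out[idx[r], ] <- cand[order(row[cand])][seq_len(k)]
    }
  }
  out
}

# Blockwise per-point sums of Euclidean distances to each label group.
# Returns list(sums = n x L matrix, sizes = group sizes).
label_dist_sums <- function(embedding, grp, n_lev, block = 1024L) {
  n <- nrow(embedding)
  sq <- rowSums(embedding^2)
  sums <- matrix(0, n, n_lev)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- -2 * tcrossprod(embedding[idx, , drop = FALSE], embedding)
    d2 <- d2 + rep(sq, each = length(idx))
    d2 <- d2 + sq[idx]
    d2[d2 < 0] <- 0
    sums[idx, ] <- t(rowsum(t(sqrt(d2)), grp))
  }
  list(sums = sums, sizes = tabulate(grp, nbins = n_lev))
}
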