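test_that("combat removes a planted additive shift between two batches", {
  withr::with_seed(1, {
    n_gene <- 50; n_col <- 200
    base <- matrix(rnorm(n_gene * n_col, 5, 1), n_gene, n_col)
    X <- cbind(base[, 1:100], base[, 101:200] + 5)
    batch <- rep(c("a", "b"), each = 100)
  })
  Xc <- combat(X, batch)
  diff <- rowMeans(Xc[, batch == "a"]) - rowMeans(Xc[, batch == "b"])
  # the planted systematic shift of 5 is removed; what remains is EB-shrunk
  # per-gene sampling noise (see vignette on why a per-gene 0.05 bound is
  # not attainable under genuine empirical-Bayes shrinkage at n = 100)
  expect_lt(abs(mean(diff)), 0.05)
  expect_lt(mean(abs(diff)), 0.2)
  expect_lt(mean(abs(diff)) / 5, 0.05)   # residual < 5% of the planted shift
  expect_true(all(is.finite(Xc)))
})

test_that("combat identity cases: one batch, zero-variance gene", {
  withr::with_seed(2, X <- matrix(rnorm(100), 10, 10))
  expect_identical(combat(X, rep("a", 10)), X)

  X2 <- rbind(X, 3)   # constant gene
  batch <- rep(c("a", "b"), each = 5)
  Xc <- combat(X2, batch)
  expect_equal(unname(Xc[11, ]), rep(3, 10))
  expect_true(all(is.finite(Xc)))
  expect_error(combat(X2, c(rep("a", 9), "b")), ">= 2 columns")
})

test_that("variable-gene selection ranks by dispersion with stated tie-break", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 60, 10, 0.5), 40, 60)
    hi <- sample(40, 10)
    X[hi, ] <- X[hi, ] + rnorm(10 * 60, 0, 5)   # 10 high-dispersion genes
  })
  rownames(X) <- sprintf("g%02d", 1:40)
  sel <- select_variable_genes(X, 10)
  expect_setequal(sel, hi)
  # clipping
  expect_length(select_variable_genes(X, 100), 40)
  # deterministic lexicographic tie-break on exact ties
  Xt <- matrix(rep(c(1, 2, 1, 2), each = 2), 2, 4, byrow = TRUE)
  rownames(Xt) <- c("zz", "aa")
  expect_identical(rownames(Xt)[select_variable_genes(Xt, 1)], "aa")
})

two_batch_scores <- function(seed, n_per = 60, sep = 8) {
  withr::with_seed(seed, {
    comp <- rep(1:2, each = n_per / 2)
    x <- cbind(rnorm(n_per, comp * sep), rnorm(n_per), rnorm(n_per))
    list(scores = rbind(x, x + matrix(rnorm(3 * n_per, 0, .3), n_per)),
         batch = rep(c("b1", "b2"), each = n_per),
         comp = c(comp, comp))
  })
}

test_that("group_and_pair links same-component groups across batches", {
  tb <- two_batch_scores(4)
  pairs <- group_and_pair(tb$scores, tb$batch, GNUM = 6, seed = 1)
  expect_gt(length(pairs), 2)
  # each mutual pair should join groups from the same planted component
  comp_of <- function(ix) {
    m <- mean(tb$comp[ix])
    round(m)
  }
  agree <- vapply(pairs, function(p)
    comp_of(p$cols1) == comp_of(p$cols2), logical(1))
  expect_gte(mean(agree), 0.9)
  # determinism
  pairs2 <- group_and_pair(tb$scores, tb$batch, GNUM = 6, seed = 1)
  expect_identical(pairs, pairs2)
})

test_that("two identical batches pair with near-zero centroid distance", {
  withr::with_seed(5, x <- matrix(rnorm(50 * 3), 50, 3))
  scores <- rbind(x, x)
  batch <- rep(c("b1", "b2"), each = 50)
  pairs <- group_and_pair(scores, batch, GNUM = 5, seed = 2)
  expect_gt(length(pairs), 0)
  dmax <- max(vapply(pairs, function(p)
    sqrt(sum((colMeans(scores[p$cols1, , drop = FALSE]) -
              colMeans(scores[p$cols2, , drop = FALSE]))^2)), numeric(1)))
  expect_lt(dmax, 1e-8)
  expect_error(group_and_pair(scores, rep("b1", 100), 5, 1), ">= 2 batches")
})

test_that("score_pcs: perfect, anti-correlated and bounded cases", {
  # construct pairs over a fake 2-PC score matrix
  scores <- cbind(c(1:6, 1:6), c(1:6, -(1:6)))
  pairs <- lapply(1:6, function(i) list(cols1 = i, cols2 = i + 6))
  cors <- score_pcs(scores, pairs, "pearson")
  expect_equal(cors[1], 1)
  expect_lte(cors[2], 0)
  expect_true(all(cors >= -1 & cors <= 1))
  expect_equal(score_pcs(scores, pairs, "spearman")[1], 1)
  expect_error(score_pcs(scores, pairs[1:2]), ">= 3 mutual pairs")
})

planted_axis_sim <- function(seed, n_gene = 60, n_per = 80, shift = 6) {
  withr::with_seed(seed, {
    # shared biology: two components present in both batches
    comp <- rep(1:2, times = n_per / 2)
    bio <- matrix(rnorm(n_gene * 2, sd = 2), n_gene, 2)
    X1 <- bio[, comp] + matrix(rnorm(n_gene * n_per), n_gene, n_per)
    X2 <- bio[, comp] + matrix(rnorm(n_gene * n_per), n_gene, n_per)
    w <- rnorm(n_gene); w <- w / sqrt(sum(w^2))
    X2 <- X2 + w * shift       # batch-only direction
    list(X = cbind(X1, X2) + 10,
         batch = rep(c("b1", "b2"), each = n_per), w = w)
  })
}

test_that("beer rejects the planted batch-only variance axis", {
  excluded <- logical(10)
  for (r in 1:10) {
    sim <- planted_axis_sim(100 + r)
    rownames(sim$X) <- sprintf("g%03d", seq_len(nrow(sim$X)))
    res <- beer(sim$X, beer_params(GNUM = 16, PCNUM = 6, GN = 60,
                                   COMBAT = FALSE, SEED = r),
                batch_labels = sim$batch)
    # find the PC aligned with the planted axis via loading correlation
    S <- gsi:::scale_rows(sim$X[res$variable_genes, , drop = FALSE])
    pca <- gsi:::pca_columns(S, 6)
    align <- abs(cor(pca$rotation, sim$w[res$variable_genes]))
    planted_pc <- which.max(align)
    excluded[r] <- !(planted_pc %in% res$retained_pcs)
  }
  expect_gte(sum(excluded), 9)
})

test_that("beer retains everything when batches are exact copies", {
  withr::with_seed(6, X <- matrix(rnorm(50 * 80, 5), 50, 80))
  rownames(X) <- sprintf("g%03d", 1:50)
  res <- beer(cbind(X, X), beer_params(GNUM = 8, PCNUM = 5, GN = 50,
                                       COMBAT = FALSE),
              batch_labels = rep(c("b1", "b2"), each = 80))
  expect_identical(res$retained_pcs, 1:5)
  expect_true(all(res$pc_correlations > 0.9))
})

test_that("single batch degrades gracefully to plain PCA", {
  withr::with_seed(7, X <- matrix(rnorm(40 * 50, 5), 40, 50))
  rownames(X) <- sprintf("g%03d", 1:40)
  res <- beer(X, beer_params(PCNUM = 5, GN = 40), batch_labels = rep("b1", 50))
  expect_identical(res$retained_pcs, 1:5)
  expect_identical(res$C_prime, X)   # COMBAT is identity with one batch
  S <- gsi:::scale_rows(X[res$variable_genes, ])
  expect_equal(res$pc_scores, gsi:::pca_columns(S, 5)$scores)
})

test_that("beer is deterministic and ROUND refinement still excludes the axis", {
  sim <- planted_axis_sim(55)
  rownames(sim$X) <- sprintf("g%03d", seq_len(nrow(sim$X)))
  p1 <- beer_params(GNUM = 16, PCNUM = 6, GN = 60, COMBAT = FALSE, ROUND = 1)
  p2 <- beer_params(GNUM = 16, PCNUM = 6, GN = 60, COMBAT = FALSE, ROUND = 2)
  r1 <- beer(sim$X, p1, batch_labels = sim$batch)
  r1b <- beer(sim$X, p1, batch_labels = sim$batch)
  expect_identical(r1$retained_pcs, r1b$retained_pcs)
  expect_identical(r1$pc_correlations, r1b$pc_correlations)
  r2 <- beer(sim$X, p2, batch_labels = sim$batch)
  S <- gsi:::scale_rows(sim$X[r2$variable_genes, , drop = FALSE])
  pca <- gsi:::pca_columns(S, 6)
  planted_pc <- which.max(abs(cor(pca$rotation, sim$w[r2$variable_genes])))
  expect_false(planted_pc %in% r1$retained_pcs)
  expect_false(planted_pc %in% r2$retained_pcs)
})
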