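# A small raster keeps these CPU-cheap; the architecture is size-agnostic.
ae_stack <- function(images, gene_ids = NULL, sample_id = "ae") {
  n <- dim(images)[1]
  structure(list(images = images,
                 gene_ids = if (is.null(gene_ids)) sprintf("g%03d", 1:n)
                            else gene_ids,
                 sample_id = sample_id,
                 height = dim(images)[2], width = dim(images)[3]),
            class = "GeneImageStack")
}

one_pattern_stack <- function(n_copies = 64, h = 24, w = 32) {
  img <- matrix(0, h, w)
  img[5:12, 8:20] <- 1
  images <- array(0, c(n_copies, h, w))
  for (i in seq_len(n_copies)) images[i, , ] <- img
  ae_stack(images)
}

test_that("seeded construction is deterministic and validates latent_dim", {
  m1 <- build_autoencoder(c(24, 32), latent_dim = 8, seed = 1)
  m2 <- build_autoencoder(c(24, 32), latent_dim = 8, seed = 1)
  expect_identical(m1$enc, m2$enc)
  expect_identical(m1$dec, m2$dec)
  m3 <- build_autoencoder(c(24, 32), latent_dim = 8, seed = 2)
  expect_false(identical(m1$enc[[1]]$W, m3$enc[[1]]$W))

  expect_error(build_autoencoder(c(24, 32), latent_dim = 0), "latent_dim")
  expect_error(build_autoencoder(c(4, 4), latent_dim = 16), "latent_dim")
})

test_that("decode inverts shapes: d-vector -> image -> d-vector", {
  m <- build_autoencoder(c(24, 32), latent_dim = 8, hidden = 16, seed = 1)
  h <- matrix(rnorm(8), 1, 8)
  img <- decode(h, m)
  expect_equal(dim(img), c(1, 24, 32))
  expect_true(all(img >= 0 & img <= 1))
  st <- ae_stack(img)
  emb <- encode(st, m)
  expect_equal(dim(emb$H), c(1, 8))
})

test_that("overfitting a single repeated image drives the loss below 0.01", {
  st <- one_pattern_stack()
  tr <- train_autoencoder(st, epochs = 200, lr = 1e-3, batch_size = 64,
                          seed = 1, latent_dim = 8, hidden = 32)
  expect_lt(tail(tr$loss_history, 1), 0.01)
  expect_true(all(is.finite(tr$loss_history)) && all(tr$loss_history >= 0))
  # reconstruction of the memorized pattern is close pixel-wise
  emb <- encode(st, tr$model)
  rec <- decode(emb$H[1, , drop = FALSE], tr$model)
  # L_recon < 0.01 bounds the *average* per-pixel error, not the max
  expect_lt(mean((rec[1, , ] - st$images[1, , ])^2), 0.01)
  expect_lt(mean(abs(rec[1, , ] - st$images[1, , ])), 0.1)
})

test_that("identical seed/data/config give identical loss histories", {
  st <- one_pattern_stack(n_copies = 16)
  tr1 <- train_autoencoder(st, epochs = 5, seed = 3, latent_dim = 4,
                           hidden = 8)
  tr2 <- train_autoencoder(st, epochs = 5, seed = 3, latent_dim = 4,
                           hidden = 8)
  expect_identical(tr1$loss_history, tr2$loss_history)
  expect_identical(tr1$model$enc, tr2$model$enc)
})

test_that("training makes progress and all-zero input is easier than random", {
  withr::with_seed(4, {
    images <- array(rbinom(40 * 24 * 32, 1, 0.3), c(40, 24, 32))
  })
  st <- ae_stack(images)
  tr <- train_autoencoder(st, epochs = 30, seed = 1, latent_dim = 8,
                          hidden = 32)
  expect_lte(min(tr$loss_history), tr$loss_history[1])
  expect_lte(tail(tr$loss_history, 1), tr$loss_history[1])

  zeros <- ae_stack(array(0, c(40, 24, 32)))
  trz <- train_autoencoder(zeros, epochs = 1, seed = 1, latent_dim = 8,
                           hidden = 32)
  expect_lte(trz$loss_history[1], tr$loss_history[1])
})

test_that("encode: shape contract, determinism, identical images map together", {
  st <- one_pattern_stack(n_copies = 10)
  m <- build_autoencoder(c(24, 32), latent_dim = 8, hidden = 16, seed = 1)
  emb <- encode(st, m)
  expect_equal(dim(emb$H), c(10, 8))
  expect_identical(rownames(emb$H), st$gene_ids)
  expect_equal(emb$H[1, ], emb$H[2, ])   # identical inputs
  expect_identical(encode(st, m)$H, emb$H)

  bad <- ae_stack(array(0, c(2, 10, 10)))
  expect_error(encode(bad, m), "shape")
})

test_that("embeddings separate two disjoint spatial pattern classes", {
  h <- 24; w <- 32; n_per <- 30
  withr::with_seed(9, {
    mk <- function(left) {
      img <- matrix(0, h, w)
      r0 <- sample(4:16, 1); c0 <- if (left) sample(1:8, 1) else sample(17:24, 1)
      img[r0:(r0 + 6), c0:(c0 + 6)] <- 1
      img
    }
    images <- array(0, c(2 * n_per, h, w))
    for (i in 1:n_per) images[i, , ] <- mk(TRUE)
    for (i in (n_per + 1):(2 * n_per)) images[i, , ] <- mk(FALSE)
  })
  st <- ae_stack(images)
  tr <- train_autoencoder(st, epochs = 60, seed = 2, latent_dim = 8,
                          hidden = 32)
  H <- encode(st, tr$model)$H
  lab <- rep(1:2, each = n_per)
  d <- as.matrix(dist(H))
  intra <- mean(d[lab == 1, lab == 1][upper.tri(d[lab == 1, lab == 1])]) +
    mean(d[lab == 2, lab == 2][upper.tri(d[lab == 2, lab == 2])])
  inter <- mean(d[lab == 1, lab == 2])
  expect_gt(inter, intra / 2)
})
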