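test_that("ARI equals the exhaustive pair-count oracle on random labelings", {
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               ari_oracle(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  withr::with_seed(1, {
    for (rep in 1:50) {
      n <- sample(4:12, 1)
      a <- sample(1:3, n, replace = TRUE)
      b <- sample(1:3, n, replace = TRUE)
      expect_equal(ari(a, b), ari_oracle(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(ari(1:5, 1:5), 1)
  # invariance to label permutation
  a <- c(1, 1, 2, 2, 3); b <- c(2, 2, 3, 3, 1)
  expect_equal(ari(a, b), 1)
  expect_error(ari(1:3, 1:4), "length")
})

test_that("NMI equals the direct-probability oracle; edge conventions hold", {
  withr::with_seed(2, {
    for (rep in 1:50) {
      n <- sample(4:12, 1)
      a <- sample(letters[1:3], n, replace = TRUE)
      b <- sample(1:4, n, replace = TRUE)
      expect_equal(nmi(a, b), nmi_oracle(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(nmi(1:6, 1:6), 1)
  expect_equal(nmi(rep(1, 6), rep(2, 6)), 1)     # both trivial
  expect_equal(nmi(rep(1, 6), rep(1:2, 3)), 0)   # one trivial
})

test_that("shuffled truth gives chance-level ARI", {
  withr::with_seed(3, {
    truth <- rep(1:4, each = 250)
    shuffled <- sample(truth)
    expect_lt(abs(ari(truth, shuffled)), 0.05)
  })
})

test_that("silhouette matches a direct O(n^2) computation and cluster::silhouette", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
    lab <- rep(1:2, each = 20)
  })
  s <- silhouette_widths(x, lab)
  # direct oracle
  d <- as.matrix(dist(x))
  oracle <- vapply(1:40, function(i) {
    a <- mean(d[i, lab == lab[i]][-match(i, which(lab == lab[i]))])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(s, oracle, tolerance = 1e-10)
  expect_gt(asw(x, lab), 0.8)
  expect_true(is.na(asw(x, rep(1, 40))))
})

test_that("blob truth scores NMI 1 and high ASW through bio_conservation", {
  be <- blob_embedding(n_per = 100)
  res <- resolution_search(be$x, as.character(be$labels), grid = c(0.25, 0.5),
                           seed = 1)
  bio <- bio_conservation(be$x, res$labels, be$labels,
                          batch_labels = rep(c("b1", "b2"), 150))
  expect_equal(bio$nmi, 1)
  expect_equal(bio$ari, 1)
  expect_gt(bio$asw_cell, 0.9)
  expect_gt(bio$clisi, 0.99)
  expect_equal(bio$iso_f1, 1)
})

test_that("isolated-label set follows the minimum-batch-count definition", {
  truth <- c(rep("a", 4), rep("b", 4), rep("c", 2))
  batch <- c("x", "x", "y", "y", "x", "x", "y", "y", "x", "x")
  expect_identical(gsi:::isolated_labels(truth, batch), "c")
  # every label in every batch: all labels share the minimum, per definition
  truth2 <- rep(c("a", "b"), 4)
  batch2 <- rep(c("x", "y"), each = 4)
  expect_setequal(gsi:::isolated_labels(truth2, batch2), c("a", "b"))
})

test_that("kBET accepts an i.i.d. two-batch null and rejects separated batches", {
  withr::with_seed(5, {
    x <- matrix(rnorm(2000), 1000, 2)
    batch <- sample(rep(c("b1", "b2"), 500))
  })
  expect_gt(kbet(x, batch, k0 = 50)$acceptance, 0.9)

  withr::with_seed(6, {
    x2 <- rbind(matrix(rnorm(1000), 500, 2),
                matrix(rnorm(1000, 30), 500, 2))
    batch2 <- rep(c("b1", "b2"), each = 500)
  })
  expect_lt(kbet(x2, batch2, k0 = 50)$acceptance, 0.1)
})

test_that("iLISI approaches the batch count on a well-mixed null", {
  withr::with_seed(7, {
    x <- matrix(rnorm(2000), 1000, 2)
    batch <- sample(rep(c("b1", "b2"), 500))
  })
  il <- lisi(x, batch, perplexity = 30)
  expect_gt(mean(il), 2 * 0.95)
  expect_true(all(il >= 1 & il <= 2 + 1e-9))
})

test_that("graph connectivity: 1 for coherent labels, < 1 for split labels", {
  be <- blob_embedding(n_per = 80)
  expect_equal(graph_connectivity(be$x, be$labels), 1)
  # one truth label spanning two distant blobs is not connected
  lab_bad <- c(rep("u", 160), rep("v", 80))
  expect_lt(graph_connectivity(be$x, lab_bad, k = 10), 1)
})

test_that("batch ASW is ~1 for interleaved batches within one label", {
  x <- cbind(seq(0, 10, length.out = 200), 0)
  batch <- rep(c("b1", "b2"), 100)   # perfectly interleaved on a line
  bm <- batch_mixing(x, batch, truth_labels = rep("L", 200))
  expect_gt(bm$batch_asw, 0.95)
  # oracle: direct silhouette of batch labels should be ~0
  s <- silhouette_widths(x, batch)
  expect_equal(bm$batch_asw, mean(1 - abs(s)), tolerance = 1e-12)
})

test_that("metrics are invariant to column order and label renaming", {
  be <- blob_embedding(n_per = 50)
  batch <- rep(c("b1", "b2"), 75)
  withr::with_seed(8, perm <- sample(150))
  r1 <- metric_report(be$x, be$labels, as.character(be$labels), batch)
  r2 <- metric_report(be$x[perm, ], be$labels[perm],
                      as.character(be$labels)[perm], batch[perm])
  for (f in c("ari", "nmi", "asw_cell", "batch_asw", "graph_connectivity"))
    expect_equal(r1[[f]], r2[[f]], tolerance = 1e-8, label = f)
  # renaming clusters changes nothing
  renamed <- c(10, 20, 30)[be$labels]
  r3 <- metric_report(be$x, renamed, as.character(be$labels), batch)
  expect_equal(r1$ari, r3$ari)
  expect_equal(r1$nmi, r3$nmi)
})
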