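test_that("activation sparsity counts inactive units", {
  expect_equal(activation_sparsity(c(1, 2, 3)), 0)
  expect_equal(activation_sparsity(c(1, 0, 2, 0)), 0.5)
  set.seed(60)
  a <- matrix(rnorm(1000), 50, 20)
  a[a < 0] <- 0
  manual <- sum(a <= 0) / length(a)
  expect_equal(activation_sparsity(a), manual)
  # invariant to positive rescaling
  expect_equal(activation_sparsity(3.7 * a), activation_sparsity(a))
  expect_error(activation_sparsity(numeric(0)), "empty")
})

test_that("activation correlations match brute-force pairwise averages", {
  # identical vectors within class -> within = 1
  v <- rnorm(10)
  acts <- cbind(v, v, -v, -v)
  res <- activation_correlations(acts, c("a", "a", "b", "b"))
  expect_equal(res$within_1, 1)
  expect_equal(res$within_2, 1)
  expect_equal(res$across, -1)

  set.seed(61)
  acts2 <- matrix(rnorm(40), 10, 4)
  cls <- c("a", "a", "b", "b")
  res2 <- activation_correlations(acts2, cls)
  expect_equal(res2$within_1, cor(acts2[, 1], acts2[, 2]))
  expect_equal(res2$within_2, cor(acts2[, 3], acts2[, 4]))
  expect_equal(res2$across,
               mean(c(cor(acts2[, 1], acts2[, 3]), cor(acts2[, 1], acts2[, 4]),
                      cor(acts2[, 2], acts2[, 3]), cor(acts2[, 2], acts2[, 4]))))
})

test_that("back-projection is the exact adjoint of the convolution map", {
  set.seed(62)
  for (cfgcase in list(list(shape = c(12, 12, 1), k = c(3, 3), s = 1, u = 4),
                       list(shape = c(20, 16, 2), k = c(5, 3), s = 2, u = 3),
                       list(shape = c(10, 10, 1), k = c(10, 10), s = 2, u = 2))) {
    layer <- list(kernel = as.integer(cfgcase$k), stride = cfgcase$s,
                  units = cfgcase$u)
    W <- matrix(rnorm(prod(cfgcase$k) * cfgcase$shape[3] * cfgcase$u),
                ncol = cfgcase$u)
    x <- matrix(rnorm(prod(cfgcase$shape[1:2]) * cfgcase$shape[3]),
                ncol = cfgcase$shape[3])
    g <- conv_forward_map(cfgcase$shape, layer, W, x)
    gr <- matrix(rnorm(length(g)), nrow(g), ncol(g))
    lhs <- sum(conv_forward_map(cfgcase$shape, layer, W, x) * gr)
    rhs <- sum(x * conv_backproject(cfgcase$shape, layer, W, gr))
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("deconvolution reconstructs through identity and zero cases", {
  set.seed(63)
  spec <- conv_net_spec(units = 2, fc_units = c(4, 4, 4))
  # single 1x1 identity-kernel layer
  spec$streams[[1]]$layers <- list(list(kernel = c(1L, 1L), stride = 1L,
                                        units = 1L))
  net <- build_network(spec)
  net$params[["s0_conv1_W"]] <- matrix(1, 1, 1)
  img <- matrix(runif(10000), 100, 100)
  m <- deconvolve(net, img, layer = 1)
  # agreement up to the batch-norm epsilon (1e-5 in the denominator)
  expect_equal(unclass(m), img, tolerance = 1e-4, ignore_attr = TRUE)

  zero <- deconvolve(net, matrix(0, 100, 100), layer = 1)
  expect_true(all(zero == 0))

  # a real (reduced) net: map has input shape and responds to the neuron arg
  net2 <- build_network(conv_net_spec(units = 3, fc_units = c(4, 4, 4)))
  m2 <- deconvolve(net2, img, layer = 2, neuron = 1)
  expect_equal(dim(m2), c(100, 100))
  expect_error(deconvolve(net2, img, layer = 9), "layer")
})

test_that("representation correlation is a Pearson correlation over pixels", {
  set.seed(64)
  a <- matrix(rnorm(100), 10, 10)
  expect_equal(representation_correlation(a, a), 1)
  expect_equal(representation_correlation(-a, a), -1)
  b <- matrix(rnorm(100), 10, 10)
  expect_equal(representation_correlation(a, b),
               cor(as.numeric(a), as.numeric(b)))
  expect_true(is.na(representation_correlation(matrix(1, 10, 10), a)))
  expect_error(representation_correlation(a, matrix(0, 5, 5)), "mismatch")
})

test_that("PCA embedding orders variance and is idempotent on its subspace", {
  set.seed(65)
  t <- rnorm(50)
  line <- outer(t, c(1, 2, -1, 0.5, 3)) +
    matrix(rnorm(250, sd = 1e-9), 50, 5)
  e <- pca_embed(line, 2)
  expect_gt(e$explained_variance[1], 0.999)

  iso <- matrix(rnorm(2000 * 4), 2000, 4)
  ei <- pca_embed(iso, 4)
  expect_lt(diff(range(ei$explained_variance)), 0.1)
  expect_true(all(diff(ei$explained_variance) <= 1e-12))

  # projecting the projection changes nothing (up to sign)
  e2 <- pca_embed(e$coords, 2)
  expect_equal(abs(cor(e$coords[, 1], e2$coords[, 1])), 1, tolerance = 1e-6)
  expect_error(pca_embed(iso[1:3, ], 5), "samples")
})

test_that("t-SNE separates well-separated clusters and is seed-deterministic", {
  set.seed(66)
  x <- rbind(matrix(rnorm(100 * 5), 100, 5),
             matrix(rnorm(100 * 5, mean = 10), 100, 5))
  labels <- rep(c("a", "b"), each = 100)
  emb <- tsne_embed(x, out_dim = 3, perplexity = 30, max_iter = 300)
  expect_equal(dim(emb$coords), c(200, 3))
  expect_true(all(is.finite(emb$coords)))
  expect_gte(knn_loo_decode(emb, labels), 95)

  set.seed(67); e1 <- tsne_embed(x, max_iter = 50)
  set.seed(67); e2 <- tsne_embed(x, max_iter = 50)
  expect_identical(e1$coords, e2$coords)
  expect_error(tsne_embed(x[1:20, ], perplexity = 30), "perplexity")
})

test_that("nearest-neighbour decoding matches exhaustive brute force", {
  # two tight clusters: perfect decoding
  set.seed(68)
  x <- rbind(matrix(rnorm(20, sd = 0.01), 10, 2),
             matrix(rnorm(20, 5, sd = 0.01), 10, 2))
  y <- rep(c("a", "b"), each = 10)
  expect_equal(knn_loo_decode(x, y), 100)

  # colinear ABAB: every nearest neighbour has the other label
  col <- cbind(c(0, 1, 2, 3), 0)
  expect_equal(knn_loo_decode(col, c("A", "B", "A", "B")), 0)

  # random case agrees exactly with an O(n^2) loop
  z <- matrix(rnorm(60), 30, 2)
  lab <- sample(c("a", "b", "c"), 30, replace = TRUE)
  brute <- 0
  for (i in 1:30) {
    best <- Inf; bj <- NA
    for (j in 1:30) {
      if (j == i) next
      d <- sum((z[i, ] - z[j, ])^2)
      if (d < best) { best <- d; bj <- j }
    }
    brute <- brute + (lab[bj] == lab[i])
  }
  expect_equal(knn_loo_decode(z, lab), 100 * brute / 30)

  # random labels decode near the majority class frequency
  set.seed(69)
  big <- matrix(rnorm(2000), 1000, 2)
  rl <- sample(c("a", "b"), 1000, replace = TRUE, prob = c(0.5, 0.5))
  expect_equal(knn_loo_decode(big, rl), 50, tolerance = 6)
})

test_that("density differences integrate to zero and localize classes", {
  set.seed(70)
  a <- matrix(rnorm(400, mean = -3, sd = 0.5), 200, 2)
  b <- matrix(rnorm(400, mean = 3, sd = 0.5), 200, 2)
  dd <- density_difference(rbind(a, b), rep(c("A", "B"), each = 200))
  cell <- diff(dd$x[1:2]) * diff(dd$y[1:2])
  expect_equal(sum(dd$z) * cell, 0, tolerance = 1e-6)
  ia <- which.min(abs(dd$x + 3)); ja <- which.min(abs(dd$y + 3))
  ib <- which.min(abs(dd$x - 3)); jb <- which.min(abs(dd$y - 3))
  expect_gt(dd$z[ia, ja], 0)
  expect_lt(dd$z[ib, jb], 0)

  # same distribution in both classes: field within 3 Monte-Carlo SEs of 0
  set.seed(71)
  xx <- matrix(rnorm(2000), 1000, 2)
  lab0 <- rep(c("A", "B"), 500)
  dd2 <- density_difference(xx, lab0, n_grid = 30)
  reps <- replicate(20, density_difference(xx, sample(lab0),
                                           n_grid = 30)$z)
  se <- apply(reps, c(1, 2), sd)
  expect_gte(mean(abs(dd2$z) <= 3 * pmax(se, 1e-12)), 0.97)
})
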