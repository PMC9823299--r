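test_that("node features are exact one-hot blocks and symmetric atoms
           share features", {
  g <- molecular_graph(c(6L, 6L, 8L, 6L, 1L, 1L, 1L, 1L, 1L, 1L),
                       rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1),
                             c(1, 5, 1), c(1, 6, 1), c(1, 7, 1),
                             c(4, 8, 1), c(4, 9, 1), c(4, 10, 1)))
  f <- featurize(g)
  widths <- c(7L, 6L, 4L, 4L, 4L)
  expect_identical(ncol(f$node), sum(widths))
  off <- cumsum(c(0, widths))
  for (b in seq_along(widths)) {
    block <- f$node[, (off[b] + 1):off[b + 1], drop = FALSE]
    expect_true(all(rowSums(block) == 1))
  }
  expect_true(all(rowSums(f$edge) == 1))
  # the molecule is symmetric: both terminal methyl carbons look alike
  expect_identical(f$node[1, ], f$node[4, ])
  # vocabulary round trip on the atomic-number block
  z_block <- f$node[, 1:7]
  decoded <- gierc:::.vocab$z[apply(z_block, 1, which.max)]
  expect_identical(decoded[1:4], c("6", "6", "8", "6"))
})

test_that("graph embeddings respect automorphisms, locality and
           permutation equivariance", {
  # symmetric molecule: atoms 1 and 4 are automorphic
  g <- molecular_graph(c(6L, 6L, 6L, 6L, 1L, 1L),
                       rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1),
                             c(1, 5, 1), c(4, 6, 1)))
  h <- embed_graph(g, width = 16L, seed = 3L)
  expect_lt(max(abs(h[1, ] - h[4, ])), 1e-6)
  expect_lt(max(abs(h[5, ] - h[6, ])), 1e-6)
  expect_gt(max(abs(h[1, ] - h[2, ])), 1e-3)

  # changing an atom four bonds away leaves the embedding unchanged
  z1 <- rep(6L, 10L); z2 <- z1; z2[10] <- 8L
  bonds <- cbind(1:9, 2:10, 1L)
  h1 <- embed_graph(molecular_graph(z1, bonds), width = 16L, seed = 3L)
  h2 <- embed_graph(molecular_graph(z2, bonds), width = 16L, seed = 3L)
  expect_lt(max(abs(h1[1:6, ] - h2[1:6, ])), 1e-10)  # > 3 bonds from atom 10
  expect_gt(max(abs(h1[7:10, ] - h2[7:10, ])), 1e-3)

  # permuting the atoms permutes the embeddings identically
  g0 <- molecular_graph(c(6L, 7L, 8L, 6L, 1L),
                        rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1),
                              c(2, 5, 1)))
  h0 <- embed_graph(g0, width = 16L, seed = 3L)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  inv <- order(perm)
  g1 <- molecular_graph(g0$atomic_numbers[inv],
                        cbind(perm[g0$bonds[, 1]], perm[g0$bonds[, 2]],
                              g0$bonds[, 3]))
  h1 <- embed_graph(g1, width = 16L, seed = 3L)
  expect_lt(max(abs(h1[perm, ] - h0)), 1e-10)
})

test_that("a noise-free autoencoder with latent width above the input
           dimension memorizes its training data", {
  set.seed(8)
  x <- matrix(rnorm(200 * 6), 200, 6)
  fit <- gierc:::ae_fit(x, enc_sizes = c(6, 128, 8), dec_sizes = c(8, 128, 6),
                        noise_percent = 0, lr = 3e-3, max_epochs = 800L,
                        lr_patience = 50L, batch_size = 32L,
                        early_stop = 800L, seed = 2L)
  expect_lt(min(fit$log$train), 1e-4)
  # validation loss improves from the first epoch to the best epoch
  expect_lt(min(fit$log$val), fit$log$val[1])
})

test_that("training is reproducible for a fixed seed and diverging loss
           aborts", {
  set.seed(8)
  x <- matrix(rnorm(100 * 4), 100, 4)
  f1 <- gierc:::ae_fit(x, enc_sizes = c(4, 8, 4), dec_sizes = c(4, 8, 4),
                       max_epochs = 5L, seed = 11L)
  f2 <- gierc:::ae_fit(x, enc_sizes = c(4, 8, 4), dec_sizes = c(4, 8, 4),
                       max_epochs = 5L, seed = 11L)
  expect_identical(f1$log$val, f2$log$val)
  expect_error(
    gierc:::ae_fit(x * 1e154, enc_sizes = c(4, 8, 4),
                   dec_sizes = c(4, 8, 4), lr = 1e3, max_epochs = 50L,
                   seed = 1L),
    "diverged")
})

test_that("the graph autoencoder reconstructs held-out small-molecule
           conformers", {
  tp <- make_template("chain", 6L, seed = 4L)
  ctx <- gierc_context(tp$graph)
  ens <- sample_ensemble(tp, 160L, seed = 31L)
  cfg <- gierc_train_config(latent_dim = 32L, hidden = 64L,
                            cmpnn_width = 16L, max_epochs = 100L,
                            batch_size = 512L, seed = 5L)
  model <- graph_ae_train(ens[1:140], tp$graph, cfg, ctx = ctx)
  tors <- vapply(ens[141:160], function(cf)
    torsion_rmsd(cf, graph_ae_reconstruct(model, cf, ctx)$conformer,
                 tp$graph), numeric(1))
  expect_lt(mean(tors), 20)
  # reconstruction refuses a mismatched graph
  other <- make_template("chain", 7L, seed = 4L)
  octx <- gierc_context(other$graph)
  expect_error(graph_ae_reconstruct(model,
                                    sample_ensemble(other, 1L)[[1]], octx),
               "different molecular graph")
})

test_that("interpolation endpoints equal direct reconstructions bitwise", {
  tp <- make_template("chain", 6L, seed = 4L)
  ctx <- gierc_context(tp$graph)
  ens <- sample_ensemble(tp, 120L, seed = 32L)
  cfg <- gierc_train_config(latent_dim = 32L, hidden = 64L,
                            cmpnn_width = 16L, max_epochs = 25L,
                            batch_size = 512L, seed = 6L)
  model <- graph_ae_train(ens, tp$graph, cfg, ctx = ctx)
  path <- interpolate_conformers(model, ens[[1]], ens[[2]], ctx, steps = 5L)
  expect_identical(length(path$conformers), 6L)
  ra <- graph_ae_reconstruct(model, ens[[1]], ctx)
  rb <- graph_ae_reconstruct(model, ens[[2]], ctx)
  expect_identical(path$conformers[[1]]$coords, ra$conformer$coords)
  expect_identical(path$conformers[[6]]$coords, rb$conformer$coords)
})

test_that("DBSCAN on a distance matrix matches brute-force components of
           core points", {
  set.seed(99)
  x <- c(rnorm(40, 0, 1), rnorm(40, 12, 1), runif(3, 5, 7))
  d <- abs(outer(x, x, "-"))
  lab <- gierc:::dbscan_matrix(d, eps = 1.5, min_samples = 4L)
  # every core point of one true mode shares a label, and the modes differ
  l1 <- unique(lab[1:40][lab[1:40] != 0])
  l2 <- unique(lab[41:80][lab[41:80] != 0])
  expect_identical(length(l1), 1L)
  expect_identical(length(l2), 1L)
  expect_false(identical(l1, l2))
  # sparse bridge points are not cores: they never merge the modes
  expect_identical(length(setdiff(unique(lab), 0L)), 2L)
})
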