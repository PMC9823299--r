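test_that("bond length table is symmetric and positive, radii fall back", {
  expect_equal(standard_bond_length(6, 6, 1), 1.508)
  # symmetry under argument swap, all tabulated pairs
  for (pr in list(c(1, 1), c(6, 1), c(6, 7), c(8, 15), c(16, 6))) {
    expect_gt(standard_bond_length(pr[1], pr[2], 1), 0)
    expect_identical(standard_bond_length(pr[1], pr[2], 1),
                     standard_bond_length(pr[2], pr[1], 1))
  }
  # pair with no table entry: sum of covalent radii
  expect_equal(standard_bond_length(5, 14, 1), 0.84 + 1.11)
  expect_error(standard_bond_length(99, 6, 1), "unsupported element")
})

test_that("graph invariants are enforced", {
  expect_error(molecular_graph(c(6, 6, 6), rbind(c(1, 2, 1), c(2, 3, 1))),
               "at least 4")
  expect_error(molecular_graph(c(6, 6, 6, 6),
                               rbind(c(1, 2, 1), c(3, 4, 1))),
               "disconnected")
  expect_error(molecular_graph(c(6, 6, 6, 6),
                               rbind(c(1, 1, 1), c(2, 3, 1), c(3, 4, 1))),
               "self-bonds")
  expect_error(molecular_graph(c(6, 6, 6, 6),
                               rbind(c(1, 2, 1), c(2, 1, 1), c(2, 3, 1),
                                     c(3, 4, 1))),
               "duplicate")
})

test_that("weighted graph distances match Floyd-Warshall brute force", {
  g <- tiny_graph(z = c(6L, 6L, 8L, 7L, 16L),
                  bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1),
                                c(4, 1, 1), c(4, 5, 1)))
  d <- weighted_graph_distances(g)
  # brute force
  n <- g$n_atoms
  w <- matrix(Inf, n, n); diag(w) <- 0
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    w[i, j] <- w[j, i] <- standard_bond_length(g$atomic_numbers[i],
                                               g$atomic_numbers[j],
                                               g$bonds[k, 3])
  }
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (w[i, k] + w[k, j] < w[i, j]) w[i, j] <- w[i, k] + w[k, j]
  expect_equal(d, w, tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("unit-weight 4-cycle distance across the ring is 2", {
  g <- molecular_graph(c(1L, 1L, 1L, 1L),
                       rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 1, 1)))
  # force unit weights by brute force on the H-H table value
  d <- weighted_graph_distances(g)
  hh <- standard_bond_length(1, 1, 1)
  expect_equal(d[1, 3], 2 * hh, tolerance = 1e-12)
  expect_equal(d[2, 4], 2 * hh, tolerance = 1e-12)
})

test_that("Coulomb matrix follows its defining formula", {
  g <- tiny_graph()
  r2d <- weighted_graph_distances(g)
  m <- coulomb_matrix(g, r2d)
  expect_equal(diag(m), 0.5 * g$atomic_numbers^2.4, tolerance = 1e-12)
  expect_equal(m[1, 2], 6 * 7 / r2d[1, 2], tolerance = 1e-12)
  expect_identical(m, t(m))
  expect_equal(0.5 * 6^2.4, 36.8585, tolerance = 1e-4)
})

test_that("canonical order is invariant under all relabelings (N = 5)", {
  g <- tiny_graph()
  ctx <- gierc_context(g)
  ref_seq <- paste(g$atomic_numbers[ctx$s$order],
                   lengths(neighbors_list(g))[ctx$s$order], collapse = " ")
  perms <- combinat_perms(5L)
  for (k in seq_len(nrow(perms))) {
    perm <- perms[k, ]
    inv <- order(perm)
    b <- cbind(perm[g$bonds[, 1]], perm[g$bonds[, 2]], g$bonds[, 3])
    g2 <- molecular_graph(g$atomic_numbers[inv], b)
    s2 <- canonical_order(coulomb_matrix(g2, weighted_graph_distances(g2)),
                          g2)
    seq2 <- paste(g2$atomic_numbers[s2$order],
                  lengths(neighbors_list(g2))[s2$order], collapse = " ")
    expect_identical(seq2, ref_seq)
    # the canonical sequence must name the same physical atoms: map back
    expect_identical(inv[s2$order], ctx$s$order)
  }
})

test_that("a heavier variant changes the affected atom's rank consistently", {
  g1 <- tiny_graph(z = c(6L, 6L, 6L, 6L, 6L))
  g2 <- tiny_graph(z = c(6L, 6L, 16L, 6L, 6L))   # heavier at position 3
  s1 <- canonical_order(coulomb_matrix(g1, weighted_graph_distances(g1)), g1)
  s2 <- canonical_order(coulomb_matrix(g2, weighted_graph_distances(g2)), g2)
  expect_identical(s2$order[1], 3L)   # heaviest row norm ranks first
  expect_false(identical(s1$order, s2$order))
})

test_that("topological neighborhood: 3 bonds, distance sort, rank ties", {
  # linear chain A-B-C-D-E(-F): from A only B, C, D are within 3 bonds
  g <- molecular_graph(rep(6L, 6L),
                       cbind(1:5, 2:6, 1L))
  ctx <- gierc_context(g)
  expect_identical(sort(ctx$nbh[[1]]), c(2L, 3L, 4L))
  expect_identical(ctx$nbh[[1]], c(2L, 3L, 4L))  # increasing r2d
  # equidistant atoms are ordered by canonical rank
  i <- 3L
  nb <- ctx$nbh[[i]]
  r <- ctx$r2d[i, nb]
  for (d in unique(r)) {
    grp <- nb[r == d]
    expect_identical(grp, grp[order(ctx$s$ranks[grp])])
  }
})

test_that("neighborhood size in a long chain never exceeds 6", {
  g <- molecular_graph(rep(6L, 20L), cbind(1:19, 2:20, 1L))
  ctx <- gierc_context(g)
  expect_true(all(ctx$m_i <= 6L))
  expect_identical(max(ctx$m_i), 6L)   # interior atoms see 3 each way
})

test_that("rotatable bonds exclude ring, terminal and multiple bonds", {
  tp <- ring24()$tp
  rb <- tp$rot_bonds
  deg <- lengths(neighbors_list(tp$graph))
  expect_true(all(deg[rb] >= 2))
  # no ring bonds: all rotatable bonds are bridges
  expect_true(all(rb[, 1] > 6 | rb[, 2] > 6 | (rb[, 1] <= 2 & rb[, 2] > 6)))
})
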