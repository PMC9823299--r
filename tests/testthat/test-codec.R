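test_that("attenuation matches its piecewise definition and is continuous", {
  expect_equal(attenuation(2.0), 0.5)
  expect_equal(attenuation(6.0), 0)
  expect_equal(attenuation(5.5), (1 / 5.5) * (0.5 * cos(pi / 2) + 0.5),
               tolerance = 1e-12)
  expect_equal(attenuation(5.5), 0.5 / 5.5, tolerance = 1e-12)  # = 0.0909..
  # continuity at both cutoffs
  expect_equal(attenuation(5 - 1e-9), attenuation(5 + 1e-9), tolerance = 1e-6)
  expect_lt(attenuation(6 - 1e-6), 1e-6)
  expect_error(attenuation(0), "positive")
  expect_error(attenuation(c(1, -2)), "positive")
})

test_that("local frame is the identity for the canonical configuration and
           equivariant under rotation", {
  am <- asym_mol()
  fr <- build_local_frame(am$ref, am$ctx, 2L)
  expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-10)
  expect_equal(det(fr$axes), 1, tolerance = 1e-10)
  set.seed(2)
  x2 <- gierc:::random_rigid_motion(am$ref$coords)
  cf2 <- conformer(x2, am$g)
  fr2 <- build_local_frame(cf2, am$ctx, 2L)
  # the same relative geometry: axes differ by the applied rotation only, so
  # local coordinates of any neighbor agree
  nb <- am$ctx$nbh[[2]][1]
  loc1 <- t(fr$axes) %*% (am$ref$coords[nb, ] - fr$origin)
  loc2 <- t(fr2$axes) %*% (cf2$coords[nb, ] - fr2$origin)
  expect_equal(loc1, loc2, tolerance = 1e-8)
})

test_that("a collinear second neighbor is promoted to the next in order", {
  # propyne-like fragment: H3C-C#C-H is linear at the central atoms; center
  # on atom 2 whose two closest neighbors are collinear
  z <- c(6L, 6L, 6L, 1L, 1L, 1L, 1L)
  bonds <- rbind(c(1, 2, 1), c(2, 3, 3), c(1, 4, 1), c(1, 5, 1),
                 c(1, 6, 1), c(3, 7, 1))
  g <- molecular_graph(z, bonds)
  ctx <- gierc_context(g)
  x <- rbind(c(-1.46, 0, 0), c(0, 0, 0), c(1.20, 0, 0),
             c(-1.83, 1.02, 0), c(-1.83, -0.51, 0.88),
             c(-1.83, -0.51, -0.88), c(2.27, 0, 0))
  cf <- conformer(x, g)
  fr <- build_local_frame(cf, ctx, 2L)
  first_two <- ctx$nbh[[2]][1:2]
  expect_false(fr$ref_b %in% first_two[abs(x[first_two, 2]) < 1e-9 &
                                       abs(x[first_two, 3]) < 1e-9])
  expect_equal(det(fr$axes), 1, tolerance = 1e-10)
})

test_that("encode_local inverts exactly through local positions", {
  am <- asym_mol()
  i <- am$ctx$s$order[1]
  slab <- encode_local(am$ref, am$ctx, i)
  pos <- local_positions_from_feature(slab, am$ctx, i)
  fr <- build_local_frame(am$ref, am$ctx, i)
  truth <- sweep(am$ref$coords[am$ctx$nbh[[i]], , drop = FALSE], 2,
                 fr$origin) %*% fr$axes
  expect_equal(unname(pos), unname(truth), tolerance = 1e-10)
  # zero-padded rows emit no position
  slab_pad <- rbind(slab, 0, 0)
  expect_identical(nrow(local_positions_from_feature(slab_pad, am$ctx, i)),
                   nrow(pos))
})

test_that("round trip is lossless across five topologies (50 conformers)", {
  specs <- list(list("chain", 10L), list("chain", 17L), list("branched", 12L),
                list("ring_plus_tail", 13L), list("peptide_like", 75L))
  for (sp in specs) {
    tp <- if (sp[[1]] == "peptide_like")
      peptide150()$tp else make_template(sp[[1]], sp[[2]], seed = 3L)
    ctx <- gierc_context(tp$graph)
    ens <- sample_ensemble(tp, 10L, seed = 13L)
    for (cf in ens) {
      dec <- gierc_decode(gierc_encode(cf, ctx = ctx), ctx = ctx)
      expect_lt(kabsch_rmsd(cf, dec), 1e-6)
      expect_lt(torsion_rmsd(cf, dec, tp$graph), 1e-6)
    }
  }
})

test_that("encoding is SE(3)-invariant to 1e-8 over 20 rigid motions", {
  r <- ring24()
  cf <- sample_ensemble(r$tp, 1L, seed = 20L)[[1]]
  f0 <- gierc_encode(cf, ctx = r$ctx)
  set.seed(77)
  for (k in 1:20) {
    cf2 <- conformer(gierc:::random_rigid_motion(cf$coords), r$tp$graph)
    f2 <- gierc_encode(cf2, ctx = r$ctx)
    expect_lt(max(abs(f2$features - f0$features)), 1e-8)
  }
  # translation by (100,100,100) exactly
  cf3 <- conformer(sweep(cf$coords, 2, c(100, 100, 100), "+"), r$tp$graph)
  expect_lt(max(abs(gierc_encode(cf3, ctx = r$ctx)$features - f0$features)),
            1e-9)
})

test_that("encoding is identical under atom relabeling", {
  am <- asym_mol()
  f0 <- gierc_encode(am$ref, ctx = am$ctx)
  set.seed(31)
  for (k in 1:10) {
    perm <- sample(am$g$n_atoms)
    rl <- relabel(am$g, am$ref, perm)
    f2 <- gierc_encode(rl$conf, ctx = gierc_context(rl$g))
    expect_identical(dim(f2$features), dim(f0$features))
    expect_lt(max(abs(f2$features - f0$features)), 1e-10)
    expect_identical(f2$fingerprint, f0$fingerprint)
  }
})

test_that("mirror images flip the z-components and nothing else", {
  am <- asym_mol()
  f0 <- gierc_encode(am$ref, ctx = am$ctx)
  xm <- am$ref$coords; xm[, 3] <- -xm[, 3]
  fm <- gierc_encode(conformer(xm, am$g), ctx = am$ctx)
  expect_lt(max(abs(fm$features[, , 1:2] - f0$features[, , 1:2])), 1e-10)
  expect_lt(max(abs(fm$features[, , 3] + f0$features[, , 3])), 1e-10)
  expect_gt(max(abs(fm$features - f0$features)), 1e-3)  # chirality seen
})

test_that("zero-noise estimates equal brute-force values from Cartesians", {
  r <- ring24()
  cf <- sample_ensemble(r$tp, 1L, seed = 40L)[[1]]
  est <- extract_internal_coords(gierc_encode(cf, ctx = r$ctx), r$ctx)
  truth <- measure_internal_coords(cf, r$ctx$plan)
  for (nm in names(est$bonds))
    expect_lt(max(abs(est$bonds[[nm]] -
                      truth$bond_lengths[as.integer(nm)])), 1e-9)
  for (nm in names(est$angles))
    expect_lt(max(abs(est$angles[[nm]] -
                      truth$bond_angles[as.integer(nm)])), 1e-9)
  for (nm in names(est$dihedrals))
    expect_lt(max(abs(wrap_angle(est$dihedrals[[nm]] -
                                 truth$dihedrals[as.integer(nm)]))), 1e-9)
})

test_that("estimate multiplicity: dihedral seen from both inner atoms,
           central bonds seen at least as often as terminal ones", {
  g <- molecular_graph(rep(6L, 10L), cbind(1:9, 2:10, 1L))
  ctx <- gierc_context(g)
  rec <- ctx$plan$records
  # a dihedral j-k-l-m is contained in at least the local structures of k, l
  for (k in 4:10) {
    centers <- ctx$est_dihedral[ctx$est_dihedral[, 1] == k, 2]
    expect_true(all(rec[k, 2:3] %in% centers))
  }
  # bond estimate counts: central bond >= terminal bond
  bond_counts <- table(factor(ctx$est_bond[, 1], levels = 2:10))
  rec_atoms <- rec[2:10, 1:2]
  central_k <- which(apply(rec_atoms, 1, function(p)
    all(p %in% 4:7))) + 1L
  terminal_k <- which(apply(rec_atoms, 1, function(p)
    any(p %in% c(1L, 10L)))) + 1L
  expect_gte(min(bond_counts[as.character(central_k)]),
             max(bond_counts[as.character(terminal_k)]))
})

test_that("neighbors beyond the outer cutoff are excluded with a warning", {
  # chain of long bonds: three P-P bonds (2.21 each) put the 3-bond neighbor
  # at 6.63 > rc = 6.0
  g <- molecular_graph(c(15L, 15L, 15L, 15L, 1L, 1L, 1L, 1L),
                       rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1),
                             c(1, 5, 1), c(1, 6, 1), c(2, 7, 1), c(4, 8, 1)))
  ctx <- gierc_context(g)
  expect_true(any(!unlist(ctx$recoverable)))
  i <- 1L
  expect_false(all(ctx$recoverable[[i]]))
  ics <- gierc:::ideal_internal_coords(g, ctx$plan)
  cf <- rebuild_cartesian(ics, g)
  slab <- encode_local(cf, ctx, i)
  # the unrecoverable neighbor's rows are exactly zero in the encoding
  expect_true(all(slab[!ctx$recoverable[[i]], ] == 0))
  expect_warning(local_positions_from_feature(slab, ctx, i), "unrecoverable")
  # decoding still succeeds losslessly: every tree tuple stays recoverable
  dec <- gierc_decode(gierc_encode(cf, ctx = ctx), ctx = ctx)
  expect_lt(kabsch_rmsd(cf, dec), 1e-6)
})

test_that("consensus clustering keeps the biggest cluster and wraps angles", {
  plan1 <- list(records = matrix(c(1L, 0L, 0L, 0L, 2L, 1L, 0L, 0L), 2, 4,
                                 byrow = TRUE))
  est <- structure(list(
    bonds = list("2" = c(1.50, 1.51, 1.49, 3.20)),
    bond_centers = list("2" = 1:4),
    angles = list(), angle_centers = list(),
    dihedrals = list(), dihedral_centers = list(),
    plan = plan1), class = "ic_estimates")
  ics <- consensus_internal_coords(est)
  expect_equal(ics$bond_lengths[2], 1.50, tolerance = 1e-12)
  # identical estimates pass through; single estimate passes through
  est$bonds <- list("2" = c(1.5, 1.5, 1.5))
  expect_equal(consensus_internal_coords(est)$bond_lengths[2], 1.5)
  est$bonds <- list("2" = 1.23)
  expect_equal(consensus_internal_coords(est)$bond_lengths[2], 1.23)
  # circular mean across the wrap point
  plan2 <- list(records = matrix(c(1L, 0L, 0L, 0L, 2L, 1L, 0L, 0L,
                                   3L, 2L, 1L, 0L, 4L, 3L, 2L, 1L), 4, 4,
                                 byrow = TRUE))
  est2 <- structure(list(
    bonds = list(), bond_centers = list(),
    angles = list(), angle_centers = list(),
    dihedrals = list("4" = c(179, -179)),
    dihedral_centers = list("4" = 1:2),
    plan = plan2), class = "ic_estimates")
  got <- consensus_internal_coords(est2)$dihedrals[4]
  expect_equal(abs(got), 180, tolerance = 1e-9)
})

test_that("1-D DBSCAN clusters agree with brute-force components", {
  set.seed(55)
  for (rep_i in 1:20) {
    x <- c(rnorm(8, 0, 0.3), rnorm(8, 5, 0.3), runif(4, -2, 7))
    eps <- 0.7
    lab <- gierc:::dbscan_linear_1d(x, eps)
    # brute force: connected components of the eps-threshold graph
    n <- length(x)
    adj <- abs(outer(x, x, "-")) <= eps
    comp <- integer(n); cid <- 0L
    for (i in seq_len(n)) {
      if (comp[i]) next
      cid <- cid + 1L; queue <- i; comp[i] <- cid
      while (length(queue)) {
        p <- queue[1]; queue <- queue[-1]
        for (q in which(adj[p, ] & comp == 0L)) {
          comp[q] <- cid; queue <- c(queue, q)
        }
      }
    }
    # same partition (labels may differ)
    expect_identical(length(unique(lab)), length(unique(comp)))
    expect_true(all(tapply(comp, lab, function(v) length(unique(v))) == 1))
  }
})

test_that("fingerprint mismatch is refused at decode", {
  r <- ring24()
  cf <- sample_ensemble(r$tp, 1L, seed = 60L)[[1]]
  f <- gierc_encode(cf, ctx = r$ctx)
  other <- make_template("chain", 10L)
  expect_error(gierc_decode(f, other$graph), "fingerprint")
})

test_that("encode refuses a padding width below the neighborhood size", {
  r <- ring24()
  cf <- sample_ensemble(r$tp, 1L, seed = 61L)[[1]]
  expect_error(gierc_encode(cf, m = 2L, ctx = r$ctx), "padding width")
  f <- gierc_encode(cf, m = r$ctx$m_min + 3L, ctx = r$ctx)
  expect_identical(dim(f$features)[2], r$ctx$m_min + 3L)
  dec <- gierc_decode(f, ctx = r$ctx)
  expect_lt(kabsch_rmsd(cf, dec), 1e-6)
})
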