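#' Smooth graph-distance attenuation factor
#'
#' Weights a neighbor's relative coordinates by its weighted graph distance
#' r: 1/r below the inner cutoff, a cosine-tapered 1/r between the cutoffs,
#' and exactly zero beyond the outer cutoff.  Continuous at both cutoffs.
#'
#' @param r weighted graph distance(s), Angstrom; must be positive.
#' @param rcs inner cutoff (default 5.0).
#' @param rc outer cutoff (default 6.0, must exceed \code{rcs}).
#' @return attenuation factor(s), same length as \code{r}.
#' @export
attenuation <- function(r, rcs = 5.0, rc = 6.0) {
  if (any(r <= 0)) stop("graph distance must be positive")
  if (!(rcs > 0 && rc > rcs)) stop("need 0 < rcs < rc")
  out <- numeric(length(r))
  near <- r <= rcs
  mid <- r > rcs & r < rc
  out[near] <- 1 / r[near]
  out[mid] <- (1 / r[mid]) *
    (0.5 * cos(pi * (r[mid] - rcs) / (rc - rcs)) + 0.5)
  out
}

# Precomputed per-graph context shared by encode and decode: weighted graph
# distances, canonical order, 3-bond neighborhoods, attenuation factors,
# Z-matrix plan and the vectorized estimate-extraction plan.
#' Precompute the encode/decode context of a molecular graph
#'
#' @param g molecular_graph.
#' @param rcs,rc attenuation cutoffs, Angstrom.
#' @return list used by \code{\link{gierc_encode}} / \code{\link{gierc_decode}}.
#' @export
gierc_context <- function(g, rcs = 5.0, rc = 6.0) {
  r2d <- weighted_graph_distances(g)
  m_coul <- coulomb_matrix(g, r2d)
  s <- canonical_order(m_coul, g)
  n <- g$n_atoms
  nbh <- lapply(seq_len(n), function(i) topo_neighborhood(g, r2d, s, i))
  m_i <- lengths(nbh)
  s2d <- lapply(seq_len(n), function(i) attenuation(r2d[i, nbh[[i]]], rcs, rc))
  recoverable <- lapply(s2d, function(v) v > 0)
  plan <- zmatrix_plan(g, s)

  # flat slot layout for local positions: slot off[c]+1 is center c (origin),
  # off[c]+1+t its t-th neighbor
  off <- c(0L, cumsum(m_i + 1L))[seq_len(n)]
  slot_of <- function(c, t) {        # position slot of atom t in c's frame
    if (t == c) off[c] + 1L else off[c] + 1L + match(t, nbh[[c]])
  }
  # membership: memb[c, t] TRUE when atom t is recoverable inside c's local
  # structure (the center itself always is)
  memb <- matrix(FALSE, n, n)
  for (c in seq_len(n)) {
    memb[c, c] <- TRUE
    memb[c, nbh[[c]][recoverable[[c]]]] <- TRUE
  }
  rec <- plan$records
  est_idx <- function(tuple_rows) {
    # tuple_rows: matrix, one row per record, columns = tuple atoms (0 = skip)
    out <- list()
    for (k in seq_len(nrow(tuple_rows))) {
      tup <- tuple_rows[k, ]
      if (any(tup == 0L)) next
      centers <- which(rowSums(memb[, tup, drop = FALSE]) == length(tup))
      if (!length(centers))
        stop("internal-coordinate tuple (",
             paste(tup, collapse = "-"), ") found in no local structure")
      for (c in centers)
        out[[length(out) + 1L]] <- c(k, c,
                                     vapply(tup, slot_of, integer(1), c = c))
    }
    do.call(rbind, out)
  }
  bond_rows <- cbind(rec[, 1], rec[, 2]); bond_rows[1, ] <- 0L
  ang_rows <- rec[, c(1, 2, 3)]; ang_rows[1:2, ] <- 0L
  dih_rows <- rec[, c(1, 2, 3, 4)]; dih_rows[1:min(3, n), ] <- 0L
  list(g = g, rcs = rcs, rc = rc, r2d = r2d, s = s, nbh = nbh, m_i = m_i,
       m_min = max(m_i), s2d = s2d, recoverable = recoverable, plan = plan,
       off = off, n_slots = sum(m_i + 1L),
       est_bond = est_idx(bond_rows),
       est_angle = est_idx(ang_rows),
       est_dihedral = if (n >= 4L) est_idx(dih_rows) else NULL,
       fingerprint = graph_fingerprint(g, s))
}

# canonical text fingerprint of the (graph, canonical order) pair; stored in
# the encoding so decode can refuse a mismatched graph
graph_fingerprint <- function(g, s) {
  r <- s$ranks
  e <- cbind(r[g$bonds[, 1]], r[g$bonds[, 2]], g$bonds[, 3])
  e[, 1:2] <- t(apply(e[, 1:2, drop = FALSE], 1, sort))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  paste(paste0(g$atomic_numbers[s$order], ".", g$formal_charges[s$order],
               collapse = ","),
        paste(e[, 1], e[, 2], e[, 3], sep = ".", collapse = ","),
        sep = ";")
}

#' Local coordinate frame of an atom
#'
#' Right-handed orthonormal frame centered on atom \code{i}: the x-axis
#' points to its graph-closest neighbor a, the z-axis is x cross (i->b) for
#' the second-closest neighbor b, and y completes the frame.  When b is
#' (nearly) collinear with a, the next atom in topological-neighborhood order
#' is promoted to b.
#'
#' @param conf conformer.
#' @param ctx context from \code{\link{gierc_context}} (or NULL to build).
#' @param i atom index.
#' @param tol collinearity tolerance on |sin(angle)|.
#' @return list(center, ref_a, ref_b, origin, axes) with axes as columns.
#' @export
build_local_frame <- function(conf, ctx = NULL, i, tol = 1e-3) {
  if (is.null(ctx)) ctx <- gierc_context(conf$graph)
  nbr <- ctx$nbh[[i]]
  if (length(nbr) < 2L)
    stop("atom ", i, " has fewer than two atoms in its 3-bond neighborhood")
  x <- conf$coords
  a <- nbr[1]
  ex <- unitv(x[a, ] - x[i, ])
  b <- NA_integer_
  for (cand in nbr[-1]) {
    v <- unitv(x[cand, ] - x[i, ])
    if (vnorm(vcross(ex, v)) > tol) { b <- cand; break }
  }
  if (is.na(b))
    stop("degenerate local frame: all neighborhood candidates of atom ", i,
         " are collinear with its first neighbor")
  ez <- unitv(vcross(ex, unitv(x[b, ] - x[i, ])))
  ey <- vcross(ez, ex)
  list(center = i, ref_a = a, ref_b = b, origin = x[i, ],
       axes = cbind(ex, ey, ez, deparse.level = 0))
}

#' Encode one atom's local structure feature
#'
#' Relative coordinates of every neighbor within three bonds, expressed in
#' the atom's local frame and scaled by attenuation/graph-distance, padded
#' with zero rows to width \code{m}.
#'
#' @param conf conformer.
#' @param ctx codec context.
#' @param i atom index.
#' @param m padding width (>= neighborhood size).
#' @return m x 3 numeric matrix.
#' @export
encode_local <- function(conf, ctx, i, m = ctx$m_min) {
  nbr <- ctx$nbh[[i]]
  if (m < length(nbr))
    stop("padding width m = ", m, " smaller than neighborhood size ",
         length(nbr), " of atom ", i)
  fr <- build_local_frame(conf, ctx, i)
  rel <- sweep(conf$coords[nbr, , drop = FALSE], 2, fr$origin) %*% fr$axes
  scale <- ctx$s2d[[i]] / ctx$r2d[i, nbr]
  out <- matrix(0, m, 3L)
  out[seq_along(nbr), ] <- rel * scale
  out
}

#' Encode a conformer into the GIE-RC tensor
#'
#' Stacks the local structure features of all atoms in canonical order into
#' an N x m x 3 tensor that is invariant to translation, rotation and atom
#' relabeling of the input, and reversible back to 3D coordinates.
#'
#' @param conf conformer.
#' @param m padding width; defaults to the largest neighborhood size of the
#'   graph (supply the dataset-wide maximum when encoding several molecules).
#' @param rcs,rc attenuation cutoffs, Angstrom.
#' @param ctx optional precomputed context (overrides rcs/rc).
#' @return object of class \code{giercm}: list(features, m, order, rcs, rc,
#'   fingerprint).
#' @export
gierc_encode <- function(conf, m = NULL, rcs = 5.0, rc = 6.0, ctx = NULL) {
  if (is.null(ctx)) ctx <- gierc_context(conf$graph, rcs, rc)
  n <- ctx$g$n_atoms
  if (is.null(m)) m <- ctx$m_min
  feats <- array(0, c(n, m, 3L))
  for (t in seq_len(n))
    feats[t, , ] <- encode_local(conf, ctx, ctx$s$order[t], m)
  structure(list(features = feats, m = m, order = ctx$s$order,
                 rcs = ctx$rcs, rc = ctx$rc, fingerprint = ctx$fingerprint),
            class = "giercm")
}

#' @export
print.giercm <- function(x, ...) {
  cat(sprintf("giercm: %d x %d x 3 feature tensor (rcs=%.1f, rc=%.1f)\n",
              dim(x$features)[1], x$m, x$rcs, x$rc))
  invisible(x)
}

#' Recover local-frame neighbor positions from a feature slab
#'
#' Exact algebraic inversion of the encoding for one atom: each recoverable
#' neighbor's local position is its feature row times r^2D / S2D(r^2D).
#' Neighbors whose attenuation is zero carry no information and are excluded.
#'
#' @param feature_slab m x 3 matrix (one atom's rows of the tensor).
#' @param ctx codec context.
#' @param i atom index the slab belongs to.
#' @return k x 3 matrix of local positions, rownames = atom indices.
#' @export
local_positions_from_feature <- function(feature_slab, ctx, i) {
  nbr <- ctx$nbh[[i]]
  rec <- ctx$recoverable[[i]]
  if (any(!rec))
    warning("atom ", i, ": ", sum(!rec),
            " neighbor(s) beyond the outer cutoff are unrecoverable")
  keep <- which(rec)
  pos <- feature_slab[keep, , drop = FALSE] *
    (ctx$r2d[i, nbr[keep]] / ctx$s2d[[i]][keep])
  rownames(pos) <- nbr[keep]
  pos
}

# fill the flat slot array of local positions for all centers
all_local_positions <- function(f, ctx) {
  n <- ctx$g$n_atoms
  p <- matrix(0, ctx$n_slots, 3L)
  ranks <- ctx$s$ranks
  for (i in seq_len(n)) {
    slab <- f$features[ranks[i], , , drop = TRUE]
    nbr <- ctx$nbh[[i]]
    keep <- which(ctx$recoverable[[i]])
    rows <- ctx$off[i] + 1L + keep
    p[rows, ] <- slab[keep, , drop = FALSE] *
      (ctx$r2d[i, nbr[keep]] / ctx$s2d[[i]][keep])
  }
  p
}

#' Per-local-structure internal coordinate estimates
#'
#' For every spanning-tree internal coordinate, computes one estimate from
#' each local structure that contains all atoms of its tuple (bond lengths
#' from pairwise distances, angles and dihedrals from the standard 3- and
#' 4-point formulas).
#'
#' @param f giercm encoding.
#' @param ctx codec context (fingerprint must match).
#' @return object of class \code{ic_estimates}: per-record lists of values
#'   and contributing center atoms.
#' @export
extract_internal_coords <- function(f, ctx) {
  if (!identical(f$fingerprint, ctx$fingerprint))
    stop("encoding fingerprint does not match the graph context")
  p <- all_local_positions(f, ctx)
  n <- ctx$g$n_atoms
  rn <- function(mm) sqrt(rowSums(mm^2))

  eb <- ctx$est_bond
  bond_val <- rn(p[eb[, 3], , drop = FALSE] - p[eb[, 4], , drop = FALSE])

  ea <- ctx$est_angle
  u <- p[ea[, 3], , drop = FALSE] - p[ea[, 4], , drop = FALSE]
  v <- p[ea[, 5], , drop = FALSE] - p[ea[, 4], , drop = FALSE]
  co <- rowSums(u * v) / (rn(u) * rn(v))
  ang_val <- deg(acos(pmax(-1, pmin(1, co))))

  ed <- ctx$est_dihedral
  if (!is.null(ed)) {
    p1 <- p[ed[, 3], , drop = FALSE]; p2 <- p[ed[, 4], , drop = FALSE]
    p3 <- p[ed[, 5], , drop = FALSE]; p4 <- p[ed[, 6], , drop = FALSE]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    rcross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                   a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                   a[, 1] * b[, 2] - a[, 2] * b[, 1])
    n1 <- rcross(b1, b2); n2 <- rcross(b2, b3)
    m1 <- rcross(n1, b2 / rn(b2))
    dih_val <- wrap_angle(deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2))))
  } else dih_val <- numeric(0)

  structure(list(
    bonds = split(bond_val, eb[, 1]),
    bond_centers = split(eb[, 2], eb[, 1]),
    angles = split(ang_val, ea[, 1]),
    angle_centers = split(ea[, 2], ea[, 1]),
    dihedrals = if (!is.null(ed)) split(dih_val, ed[, 1]) else list(),
    dihedral_centers = if (!is.null(ed)) split(ed[, 2], ed[, 1]) else list(),
    plan = ctx$plan
  ), class = "ic_estimates")
}

#' Consensus internal coordinates from per-local-structure estimates
#'
#' Per internal coordinate, clusters the 1-D estimates with DBSCAN
#' (min_samples = 1; circular distance for dihedrals), keeps only the biggest
#' cluster and returns its mean (circular mean for angles and dihedrals).
#' This removes noisy or unreasonable estimates when the encoding has been
#' perturbed; at zero noise every estimate agrees and the filter is a no-op.
#'
#' @param est ic_estimates.
#' @param eps_bond,eps_angle,eps_dihedral DBSCAN radii (defaults 0.1 Angstrom,
#'   20 degrees, 20 degrees).
#' @return internal_coords object.
#' @export
consensus_internal_coords <- function(est, eps_bond = 0.1, eps_angle = 20,
                                      eps_dihedral = 20) {
  stopifnot(eps_bond > 0, eps_angle > 0, eps_dihedral > 0)
  n <- nrow(est$plan$records)
  bl <- rep(NA_real_, n); ba <- rep(NA_real_, n); dh <- rep(NA_real_, n)
  for (nm in names(est$bonds)) {
    v <- est$bonds[[nm]]
    keep <- biggest_cluster(dbscan_linear_1d(v, eps_bond))
    bl[as.integer(nm)] <- mean(v[keep])
  }
  for (nm in names(est$angles)) {
    v <- est$angles[[nm]]
    keep <- biggest_cluster(dbscan_linear_1d(v, eps_angle))
    ba[as.integer(nm)] <- circular_mean(v[keep])
  }
  for (nm in names(est$dihedrals)) {
    v <- est$dihedrals[[nm]]
    keep <- biggest_cluster(dbscan_circular_1d(v, eps_dihedral))
    dh[as.integer(nm)] <- circular_mean(v[keep])
  }
  structure(list(plan = est$plan, bond_lengths = bl, bond_angles = ba,
                 dihedrals = dh), class = "internal_coords")
}

#' Decode a GIE-RC tensor back to Cartesian coordinates
#'
#' Composition of \code{\link{local_positions_from_feature}},
#' \code{\link{extract_internal_coords}},
#' \code{\link{consensus_internal_coords}} and
#' \code{\link{rebuild_cartesian}}.  Lossless (to numerical precision) for an
#' unperturbed encoding; robust to elementwise noise through the consensus
#' filter.
#'
#' @param f giercm encoding.
#' @param g molecular_graph the encoding was produced for.
#' @param ctx optional precomputed context (saves recomputation across many
#'   decodes of the same graph).
#' @param eps_bond,eps_angle,eps_dihedral consensus DBSCAN radii.
#' @return conformer.
#' @export
gierc_decode <- function(f, g = NULL, ctx = NULL, eps_bond = 0.1,
                         eps_angle = 20, eps_dihedral = 20) {
  if (is.null(ctx)) {
    if (is.null(g)) stop("supply the molecular graph or a context")
    ctx <- gierc_context(g, f$rcs, f$rc)
  }
  if (!identical(f$fingerprint, ctx$fingerprint))
    stop("encoding fingerprint does not match the graph")
  est <- extract_internal_coords(f, ctx)
  ics <- consensus_internal_coords(est, eps_bond, eps_angle, eps_dihedral)
  rebuild_cartesian(ics, ctx$g)
}
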