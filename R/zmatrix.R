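#' Conformer
#'
#' An N x 3 Cartesian coordinate matrix (Angstrom) bound to the molecular
#' graph it instantiates.
#'
#' @param coords N x 3 numeric matrix.
#' @param graph molecular_graph with matching atom count.
#' @param check validate that no two bonded atoms coincide (distance >
#'   0.1 Angstrom).  Input structures are always checked; decoded outputs of
#'   noisy representations are built with \code{check = FALSE} since a
#'   heavily perturbed reconstruction is a measurement, not an input.
#' @return object of class \code{conformer}.
#' @export
conformer <- function(coords, graph, check = TRUE) {
  coords <- as.matrix(coords)
  if (nrow(coords) != graph$n_atoms || ncol(coords) != 3L)
    stop("coordinate matrix must be n_atoms x 3")
  if (check) {
    b <- graph$bonds
    d <- sqrt(rowSums((coords[b[, 1], , drop = FALSE] -
                       coords[b[, 2], , drop = FALSE])^2))
    if (any(d <= 0.1))
      stop("bonded atoms closer than 0.1 Angstrom (bond ",
           which.min(d), ")")
  }
  structure(list(coords = coords, graph = graph), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("conformer: %d atoms\n", nrow(x$coords)))
  invisible(x)
}

# Spanning-tree Z-matrix construction plan.
#
# Atoms are visited breadth-first from the first atom of the canonical order,
# children in canonical-rank order.  Each placement record holds the atom and
# up to three reference atoms (r1 = tree parent; r2, r3 complete a connected
# reference chain, preferring tree ancestors, falling back to the
# earliest-placed graph neighbor so that every (bond, angle, dihedral) tuple
# spans at most three bonds and is therefore contained in at least one
# 3-bond local structure).
zmatrix_plan <- function(g, s) {
  n <- g$n_atoms
  nb <- neighbors_list(g)
  root <- s$order[1]
  parent <- integer(n)
  ord <- integer(n)
  pos <- integer(n)           # placement position of each atom
  visited <- logical(n)
  queue <- root; visited[root] <- TRUE
  k <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    k <- k + 1L; ord[k] <- v; pos[v] <- k
    ch <- nb[[v]][!visited[nb[[v]]]]
    ch <- ch[order(s$ranks[ch])]
    visited[ch] <- TRUE
    parent[ch] <- v
    queue <- c(queue, ch)
  }

  placed_before <- function(a, x) pos[a] > 0 && pos[a] < pos[x]
  rec <- matrix(0L, n, 4L, dimnames = list(NULL, c("atom", "r1", "r2", "r3")))
  rec[, 1] <- ord
  for (k in 2:n) {
    x <- ord[k]
    r1 <- parent[x]
    rec[k, 2] <- r1
    if (k == 2L) next
    # r2: prefer r1's tree parent, else earliest-placed other neighbor of r1
    r2 <- parent[r1]
    if (r2 == 0L || !placed_before(r2, x)) {
      cand <- setdiff(nb[[r1]], x)
      cand <- cand[vapply(cand, placed_before, logical(1), x = x)]
      if (!length(cand)) stop("no angle reference for atom ", x)
      r2 <- cand[which.min(pos[cand])]
    }
    rec[k, 3] <- r2
    if (k == 3L) next
    # r3: prefer r2's tree parent, else earliest-placed neighbor of r2,
    # else another earliest-placed neighbor of r1 (improper dihedral)
    r3 <- parent[r2]
    if (r3 == 0L || r3 %in% c(x, r1) || !placed_before(r3, x)) {
      cand <- setdiff(nb[[r2]], c(x, r1))
      cand <- cand[vapply(cand, placed_before, logical(1), x = x)]
      if (!length(cand)) {
        cand <- setdiff(nb[[r1]], c(x, r2))
        cand <- cand[vapply(cand, placed_before, logical(1), x = x)]
      }
      if (!length(cand)) stop("no dihedral reference for atom ", x)
      r3 <- cand[which.min(pos[cand])]
    }
    rec[k, 4] <- r3
  }
  list(records = rec, order = ord, parent = parent)
}

#' Measure spanning-tree internal coordinates of a conformer
#'
#' Computes the (bond, angle, dihedral) values of every placement record of
#' the spanning-tree Z-matrix directly from Cartesian coordinates.
#'
#' @param conf conformer.
#' @param plan Z-matrix plan (internal); built from the graph when NULL.
#' @return object of class \code{internal_coords}: the plan plus
#'   \code{bond_lengths} (Angstrom), \code{bond_angles} (degrees),
#'   \code{dihedrals} (degrees).
#' @export
measure_internal_coords <- function(conf, plan = NULL) {
  g <- conf$graph
  if (is.null(plan)) {
    r2d <- weighted_graph_distances(g)
    plan <- zmatrix_plan(g, canonical_order(coulomb_matrix(g, r2d), g))
  }
  x <- conf$coords
  n <- g$n_atoms
  rec <- plan$records
  bl <- rep(NA_real_, n); ba <- rep(NA_real_, n); dh <- rep(NA_real_, n)
  for (k in 2:n) {
    a <- rec[k, 1]; r1 <- rec[k, 2]
    bl[k] <- vnorm(x[a, ] - x[r1, ])
    if (k >= 3L) ba[k] <- bond_angle(x[a, ], x[r1, ], x[rec[k, 3], ])
    if (k >= 4L) dh[k] <- dihedral_angle(x[a, ], x[r1, ], x[rec[k, 3], ],
                                         x[rec[k, 4], ])
  }
  structure(list(plan = plan, bond_lengths = bl, bond_angles = ba,
                 dihedrals = dh), class = "internal_coords")
}

#' Rebuild Cartesian coordinates from internal coordinates
#'
#' Sequential natural-extension-reference-frame placement: the first atom at
#' the origin, the second along +x, the third in the xy-plane, and every
#' later atom from its (bond, angle, dihedral) against the three reference
#' atoms of its placement record.
#'
#' @param ics internal_coords object.
#' @param g molecular_graph.
#' @return conformer satisfying the input internal coordinates.
#' @export
rebuild_cartesian <- function(ics, g) {
  rec <- ics$plan$records
  n <- nrow(rec)
  x <- matrix(NA_real_, n, 3L)
  x[rec[1, 1], ] <- c(0, 0, 0)
  x[rec[2, 1], ] <- c(ics$bond_lengths[2], 0, 0)
  if (n >= 3L) {
    r1 <- x[rec[3, 2], ]; r2 <- x[rec[3, 3], ]
    th <- rad(ics$bond_angles[3])
    u <- unitv(r2 - r1)
    w <- c(-u[2], u[1], 0)   # in-plane perpendicular (u lies along x here)
    if (vnorm(w) < 1e-12) w <- c(0, 1, 0) else w <- unitv(w)
    x[rec[3, 1], ] <- r1 + ics$bond_lengths[3] * (cos(th) * u + sin(th) * w)
  }
  if (n >= 4L) for (k in 4:n) {
    d  <- ics$bond_lengths[k]
    th <- rad(ics$bond_angles[k])
    ph <- rad(ics$dihedrals[k])
    C <- x[rec[k, 2], ]; B <- x[rec[k, 3], ]; A <- x[rec[k, 4], ]
    bc <- unitv(C - B)
    ab <- B - A
    nrm <- vcross(ab, bc)
    if (vnorm(nrm) < 1e-10)
      stop("degenerate placement: reference atoms for atom ", rec[k, 1],
           " are collinear")
    nrm <- unitv(nrm)
    m2 <- vcross(nrm, bc)
    d2 <- c(-d * cos(th), d * sin(th) * cos(ph), -d * sin(th) * sin(ph))
    x[rec[k, 1], ] <- C + d2[1] * bc + d2[2] * m2 + d2[3] * nrm
  }
  conformer(x, g, check = FALSE)
}

# largest deviation between rebuilt and tabulated closure (non-tree) bond
# lengths: a diagnostic, never repaired
ring_closure_diagnostic <- function(conf, plan = NULL) {
  g <- conf$graph
  if (is.null(plan)) {
    r2d <- weighted_graph_distances(g)
    plan <- zmatrix_plan(g, canonical_order(coulomb_matrix(g, r2d), g))
  }
  tree_pairs <- cbind(plan$records[-1, 1], plan$records[-1, 2])
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  closure <- g$bonds[!(key(g$bonds) %in% key(tree_pairs)), , drop = FALSE]
  if (nrow(closure) == 0L) return(0)
  d3 <- sqrt(rowSums((conf$coords[closure[, 1], , drop = FALSE] -
                      conf$coords[closure[, 2], , drop = FALSE])^2))
  ref <- vapply(seq_len(nrow(closure)), function(k)
    standard_bond_length(g$atomic_numbers[closure[k, 1]],
                         g$atomic_numbers[closure[k, 2]], closure[k, 3]),
    numeric(1))
  max(abs(d3 - ref))
}
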