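#' Molecular graph
#'
#' The 2D topology everything else derives from: per-atom atomic numbers,
#' formal charges, chirality and hybridization tags, plus a bond list with
#' formal bond orders.  The graph must be connected, free of self-bonds and
#' duplicate bonds, and have at least four atoms.
#'
#' @param atomic_numbers integer vector of atomic numbers Z.
#' @param bonds matrix (or data.frame) with columns i, j, order; 1-based atom
#'   indices, i < j enforced internally.
#' @param formal_charges integer per atom (default 0).
#' @param chirality character per atom, one of "none", "R", "S" (default
#'   "none").
#' @param hybridization character per atom ("sp", "sp2", "sp3"); when NULL it
#'   is assigned from the incident bond orders (any triple bond or two
#'   doubles: sp; any double/aromatic: sp2; otherwise sp3).
#' @return an object of class \code{molecular_graph}.
#' @export
molecular_graph <- function(atomic_numbers, bonds, formal_charges = NULL,
                            chirality = NULL, hybridization = NULL) {
  z <- as.integer(atomic_numbers)
  n <- length(z)
  if (n < 4L) stop("a molecular graph needs at least 4 atoms")
  element_symbol(z)  # errors early on unsupported elements
  b <- as.matrix(bonds)
  if (ncol(b) == 2L) b <- cbind(b, 1L)
  storage.mode(b) <- "integer"
  if (any(b[, 1] == b[, 2])) stop("self-bonds are not allowed")
  ij <- t(apply(b[, 1:2, drop = FALSE], 1L, sort))
  b <- cbind(ij, b[, 3])
  colnames(b) <- c("i", "j", "order")
  if (anyDuplicated(b[, 1:2, drop = FALSE]))
    stop("duplicate bonds in bond list")
  if (any(b[, 1:2] < 1L) || any(b[, 1:2] > n))
    stop("bond indices out of range")
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]

  if (is.null(formal_charges)) formal_charges <- integer(n)
  if (is.null(chirality)) chirality <- rep("none", n)
  if (is.null(hybridization)) {
    hybridization <- vapply(seq_len(n), function(i) {
      o <- b[b[, 1] == i | b[, 2] == i, 3]
      if (any(o == 3L) || sum(o == 2L) >= 2L) "sp"
      else if (any(o >= 2L)) "sp2" else "sp3"
    }, character(1))
  }

  g <- structure(list(
    atomic_numbers = z,
    formal_charges = as.integer(formal_charges),
    chirality_tags = as.character(chirality),
    hybridizations = as.character(hybridization),
    bonds = b,
    n_atoms = n
  ), class = "molecular_graph")

  comp <- igraph::components(as_igraph(g))
  if (comp$no > 1L)
    stop("molecular graph is disconnected (components: ",
         paste(comp$csize, collapse = ", "), " atoms)")
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("molecular_graph: %d atoms, %d bonds (%s)\n",
              x$n_atoms, nrow(x$bonds),
              paste(names(table(element_symbol(x$atomic_numbers))),
                    table(element_symbol(x$atomic_numbers)),
                    sep = "", collapse = " ")))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_edgelist(g$bonds[, 1:2, drop = FALSE], directed = FALSE)
}

#' Atom adjacency list
#' @param g molecular_graph.
#' @return list of integer vectors, neighbors of each atom.
#' @export
neighbors_list <- function(g) {
  nb <- vector("list", g$n_atoms)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Weighted 2D graph distances
#'
#' Shortest bond-path distance between every atom pair, where each bond
#' contributes its reference length from \code{\link{standard_bond_length}}
#' (Dijkstra on the bond graph).  This is a purely topological quantity:
#' no 3D coordinates are involved.
#'
#' @param g molecular_graph.
#' @return symmetric N x N matrix in Angstrom, zero diagonal.
#' @export
weighted_graph_distances <- function(g) {
  w <- vapply(seq_len(nrow(g$bonds)), function(k) {
    standard_bond_length(g$atomic_numbers[g$bonds[k, 1]],
                         g$atomic_numbers[g$bonds[k, 2]],
                         g$bonds[k, 3])
  }, numeric(1))
  d <- igraph::distances(as_igraph(g), weights = w, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Coulomb matrix from graph distances
#'
#' M_ii = 0.5 * Z_i^2.4, M_ij = Z_i * Z_j / r_ij^2D, with r^2D the weighted
#' graph distance.  Used only to derive a canonical atom order.
#'
#' @param g molecular_graph.
#' @param r2d matrix from \code{\link{weighted_graph_distances}}.
#' @return symmetric N x N matrix.
#' @export
coulomb_matrix <- function(g, r2d) {
  z <- g$atomic_numbers
  if (!all(dim(r2d) == g$n_atoms)) stop("dimension mismatch")
  m <- outer(z, z) / r2d
  diag(m) <- 0.5 * z^2.4
  m
}

#' Canonical atom order
#'
#' Derives a deterministic, relabeling-invariant atom order S from the
#' Coulomb matrix: atoms are ranked by descending row norm of M, with ties
#' broken by atomic number, degree, and iterative (Weisfeiler-Lehman style)
#' refinement over sorted neighbor keys.  Atoms that remain tied after
#' refinement are graph-automorphic; their relative order falls back to the
#' input index, which is reproducible for a fixed input.
#'
#' @param m Coulomb matrix.
#' @param g molecular_graph.
#' @return list with \code{order} (atom indices in canonical sequence) and
#'   \code{ranks} (position of each atom in that sequence), class
#'   \code{canonical_order}.
#' @export
canonical_order <- function(m, g) {
  n <- g$n_atoms
  nb <- neighbors_list(g)
  deg <- lengths(nb)
  rn <- sqrt(rowSums(m^2))
  # initial color classes: row norm desc, then Z desc, then degree desc
  o <- order(-round(rn, 9), -g$atomic_numbers, -deg)
  key0 <- sprintf("%.9f|%d|%d", rn, g$atomic_numbers, deg)
  color <- match(key0, key0[o][!duplicated(key0[o])])
  # refine: append sorted neighbor colors until stable; classes are ordered
  # by (old color, signature) so refinement only splits, never reorders
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      paste(color[i], paste(sort(color[nb[[i]]]), collapse = ","), sep = "|")
    }, character(1))
    o <- order(color, sig)
    new_color <- match(sig, unique(sig[o]))
    if (identical(new_color, color)) break
    color <- new_color
  }
  ord <- order(color, seq_len(n))
  structure(list(order = ord, ranks = order(ord)), class = "canonical_order")
}

#' Topological neighborhood of an atom
#'
#' All atoms within three bonds of atom \code{i}, sorted by weighted graph
#' distance (ascending); atoms at equal weighted distance are ordered by
#' their canonical rank.
#'
#' @param g molecular_graph.
#' @param r2d weighted graph distance matrix.
#' @param s canonical_order.
#' @param i atom index.
#' @return integer vector of neighbor atom indices.
#' @export
topo_neighborhood <- function(g, r2d, s, i) {
  hops <- igraph::distances(as_igraph(g), v = i, algorithm = "unweighted")[1, ]
  j <- setdiff(which(hops <= 3), i)
  j[order(r2d[i, j], s$ranks[j])]
}

# Bonds whose removal disconnects the graph (i.e. acyclic bonds) with both
# endpoints non-terminal and bond order 1: the rotatable set.
rotatable_bonds <- function(g) {
  ig <- as_igraph(g)
  br <- igraph::bridges(ig)
  el <- igraph::as_edgelist(ig)[br, , drop = FALSE]
  deg <- lengths(neighbors_list(g))
  keep <- logical(nrow(el))
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1]; j <- el[k, 2]
    ord <- g$bonds[g$bonds[, 1] == min(i, j) & g$bonds[, 2] == max(i, j), 3]
    keep[k] <- deg[i] >= 2L && deg[j] >= 2L && ord == 1L
  }
  el <- el[keep, , drop = FALSE]
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# One canonical proper dihedral per rotatable bond: flanking atoms are the
# lowest-canonical-rank neighbors on each side.
canonical_torsions <- function(g, s = NULL) {
  if (is.null(s)) {
    r2d <- weighted_graph_distances(g)
    s <- canonical_order(coulomb_matrix(g, r2d), g)
  }
  nb <- neighbors_list(g)
  rb <- rotatable_bonds(g)
  if (nrow(rb) == 0L) stop("no torsions: molecule has no rotatable bonds")
  quads <- matrix(0L, nrow(rb), 4L)
  for (k in seq_len(nrow(rb))) {
    p <- rb[k, 1]; q <- rb[k, 2]
    a <- setdiff(nb[[p]], q); a <- a[which.min(s$ranks[a])]
    b <- setdiff(nb[[q]], p); b <- b[which.min(s$ranks[b])]
    quads[k, ] <- c(a, p, q, b)
  }
  quads
}
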