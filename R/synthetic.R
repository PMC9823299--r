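# Synthetic molecular templates and conformer ensembles with controlled
# multi-modal torsion structure.  These stand in for MD-derived ensembles:
# torsions are drawn from explicit mixtures (no force field, no energies),
# bonds/angles get small Gaussian jitter, and Cartesian coordinates are
# rebuilt through the same spanning-tree machinery the codec uses.

.valence <- c("1" = 1, "6" = 4, "7" = 3, "8" = 2, "15" = 5, "16" = 2)

ideal_angle <- function(hyb) switch(hyb, sp = 179, sp2 = 120, 109.471)

# heavy-atom skeletons ------------------------------------------------------

skeleton_chain <- function(n_heavy, seed) {
  z <- local_seed(seed, {
    zz <- sample(c(6L, 6L, 6L, 7L, 8L, 16L), n_heavy, replace = TRUE)
    zz
  })
  bonds <- cbind(seq_len(n_heavy - 1L), 2:n_heavy, 1L)
  list(z = z, bonds = bonds)
}

skeleton_branched <- function(n_heavy, seed) {
  n_bb <- max(4L, ceiling(2 * n_heavy / 3))
  n_br <- n_heavy - n_bb
  local_seed(seed, {
    z <- c(rep(6L, n_bb), sample(c(6L, 7L, 8L), n_br, replace = TRUE))
    bonds <- cbind(seq_len(n_bb - 1L), 2:n_bb, 1L)
    # attach branches to interior backbone carbons with free valence
    used <- integer(n_bb)
    used[2:(n_bb - 1)] <- 2L; used[c(1, n_bb)] <- 1L
    for (k in seq_len(n_br)) {
      ok <- which(used < 3L & seq_len(n_bb) > 1L & seq_len(n_bb) < n_bb)
      at <- if (length(ok) > 1L) sample(ok, 1L) else ok
      bonds <- rbind(bonds, c(at, n_bb + k, 1L))
      used[at] <- used[at] + 1L
    }
    list(z = z, bonds = bonds)
  })
}

# aromatic 6-ring with a methyl and a phosphate-ester-like tail; with the
# default n_heavy = 13 and hydrogens this is a 24-atom system
skeleton_ring_tail <- function(n_heavy, seed) {
  if (n_heavy < 8L) stop("ring_plus_tail needs at least 8 heavy atoms")
  z <- rep(6L, 6L)
  bonds <- cbind(1:6, c(2:6, 1L), 4L)              # aromatic ring
  nxt <- 7L
  z <- c(z, 6L); bonds <- rbind(bonds, c(2L, nxt, 1L))  # ring methyl
  nxt <- nxt + 1L
  tail_len <- n_heavy - 7L
  # tail pattern from ring atom 1: CH2 - O - P(=O)(OH)(OH), then carbons
  pat_z <- c(6L, 8L, 15L)
  attach <- 1L
  placed <- 0L
  p_atom <- NA_integer_
  while (placed < tail_len) {
    if (placed < 3L) {
      z <- c(z, pat_z[placed + 1L])
      bonds <- rbind(bonds, c(attach, nxt, 1L))
      if (pat_z[placed + 1L] == 15L) p_atom <- nxt
      attach <- nxt
    } else if (placed < 6L && !is.na(p_atom)) {
      z <- c(z, 8L)                                  # P oxygens
      ord <- if (placed == 3L) 2L else 1L            # =O then two OH
      bonds <- rbind(bonds, c(p_atom, nxt, ord))
      attach <- nxt
    } else {
      z <- c(z, 6L)                                  # carbon extension
      bonds <- rbind(bonds, c(attach, nxt, 1L))
      attach <- nxt
    }
    nxt <- nxt + 1L; placed <- placed + 1L
  }
  list(z = z, bonds = bonds)
}

# Ace-(Ala/Gly/Ser)n-Nme backbone; n_gly/n_ser tune the atom count (a
# glycine removes one heavy atom and two hydrogens relative to alanine, a
# serine adds one heavy atom at equal hydrogen count)
skeleton_peptide <- function(n_heavy, n_gly = 0L, n_ser = 0L) {
  r <- (n_heavy - 5L + n_gly - n_ser) / 5L
  if (r != round(r) || r < 1L)
    stop("peptide_like: cannot reach ", n_heavy, " heavy atoms with ",
         n_gly, " glycines and ", n_ser, " serines")
  r <- as.integer(r)
  kinds <- rep("ala", r)
  if (n_gly > 0L) kinds[seq(2L, by = 2L, length.out = n_gly)] <- "gly"
  if (n_ser > 0L) kinds[seq(3L, by = 2L, length.out = n_ser)] <- "ser"
  z <- integer(0); bonds <- matrix(0L, 0L, 3L)
  add <- function(zz) { z <<- c(z, zz); length(z) }
  bond <- function(i, j, o = 1L) bonds <<- rbind(bonds, c(i, j, o))
  cme <- add(6L); cco <- add(6L); o <- add(8L)       # acetyl cap
  bond(cme, cco); bond(cco, o, 2L)
  prev_c <- cco
  for (k in seq_len(r)) {
    nn <- add(7L); bond(prev_c, nn)
    ca <- add(6L); bond(nn, ca)
    if (kinds[k] != "gly") {
      cb <- add(6L); bond(ca, cb)
      if (kinds[k] == "ser") { og <- add(8L); bond(cb, og) }
    }
    cc <- add(6L); bond(ca, cc)
    oo <- add(8L); bond(cc, oo, 2L)
    prev_c <- cc
  }
  nn <- add(7L); bond(prev_c, nn)
  cme2 <- add(6L); bond(nn, cme2)
  list(z = z, bonds = bonds)
}

add_hydrogens <- function(z, bonds) {
  n <- length(z)
  used <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    w <- if (bonds[k, 3] == 4L) 1.5 else bonds[k, 3]
    used[bonds[k, 1]] <- used[bonds[k, 1]] + w
    used[bonds[k, 2]] <- used[bonds[k, 2]] + w
  }
  for (i in seq_len(n)) {
    nh <- round(.valence[as.character(z[i])] - used[i])
    if (nh < 0)
      stop("valence exceeded at atom ", i)
    for (k in seq_len(nh)) {
      z <- c(z, 1L)
      bonds <- rbind(bonds, c(i, length(z), 1L))
    }
  }
  list(z = z, bonds = bonds)
}

# ideal internal coordinates for a graph: table bond lengths, hybridization
# angles, ring dihedrals 0, substituents staggered/planar
ideal_internal_coords <- function(g, plan) {
  rec <- plan$records
  n <- nrow(rec)
  ig <- as_igraph(g)
  bridge_idx <- igraph::bridges(ig)
  el <- igraph::as_edgelist(ig)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ring_bond <- setdiff(key(el[, 1], el[, 2]),
                       key(el[bridge_idx, 1], el[bridge_idx, 2]))
  is_ring <- function(i, j) key(i, j) %in% ring_bond
  bl <- rep(NA_real_, n); ba <- rep(NA_real_, n); dh <- rep(NA_real_, n)
  border <- function(i, j) {
    g$bonds[g$bonds[, 1] == min(i, j) & g$bonds[, 2] == max(i, j), 3]
  }
  for (k in 2:n) {
    a <- rec[k, 1]; r1 <- rec[k, 2]
    bl[k] <- standard_bond_length(g$atomic_numbers[a], g$atomic_numbers[r1],
                                  border(a, r1))
    if (k >= 3L) ba[k] <- ideal_angle(g$hybridizations[r1])
  }
  if (n >= 4L) {
    grp <- paste(rec[4:n, 2], rec[4:n, 3], rec[4:n, 4])
    for (gk in unique(grp)) {
      ks <- (4:n)[grp == gk]
      r1 <- rec[ks[1], 2]
      vals <- if (g$hybridizations[r1] == "sp2") c(180, 0, 90)
              else c(180, 60, -60, 120)
      ringk <- vapply(ks, function(k)
        is_ring(rec[k, 1], rec[k, 2]) && is_ring(rec[k, 2], rec[k, 3]) &&
        is_ring(rec[k, 3], rec[k, 4]), logical(1))
      dh[ks[ringk]] <- 0
      if (any(ringk)) vals <- setdiff(vals, 0)
      dh[ks[!ringk]] <- vals[seq_len(sum(!ringk))]
    }
  }
  structure(list(plan = plan, bond_lengths = bl, bond_angles = ba,
                 dihedrals = dh), class = "internal_coords")
}

#' Build a synthetic molecular template
#'
#' Deterministically constructs a connected, valence-plausible molecular
#' graph of the requested family plus an ideal-geometry reference conformer
#' (tabulated bond lengths, tetrahedral/trigonal angles, staggered or planar
#' torsions, planar aromatic rings).
#'
#' @param kind one of "chain", "branched", "ring_plus_tail", "peptide_like".
#' @param n_heavy number of heavy (non-hydrogen) atoms.
#' @param include_h fill remaining valences with explicit hydrogens.
#' @param seed integer seed (element choice for chain/branched kinds).
#' @param n_gly,n_ser peptide_like only: number of glycine-like / serine-like
#'   residues replacing alanine-like ones (tunes the exact atom count).
#' @return object of class \code{mol_template}: list(graph, ref, plan,
#'   rot_bonds, axis_sign, quads).
#' @export
make_template <- function(kind = c("chain", "branched", "ring_plus_tail",
                                   "peptide_like"),
                          n_heavy, include_h = TRUE, seed = 1L,
                          n_gly = 0L, n_ser = 0L) {
  kind <- match.arg(kind)
  if (n_heavy < 4L) stop("need at least 4 heavy atoms")
  sk <- switch(kind,
    chain = skeleton_chain(n_heavy, seed),
    branched = skeleton_branched(n_heavy, seed),
    ring_plus_tail = skeleton_ring_tail(n_heavy, seed),
    peptide_like = skeleton_peptide(n_heavy, n_gly, n_ser))
  if (include_h) sk <- add_hydrogens(sk$z, sk$bonds)
  g <- molecular_graph(sk$z, sk$bonds)
  ctx <- gierc_context(g)
  ics <- ideal_internal_coords(g, ctx$plan)
  ref <- rebuild_cartesian(ics, g)

  rb <- rotatable_bonds(g)
  quads <- if (nrow(rb)) canonical_torsions(g, ctx$s) else
    matrix(0L, 0L, 4L)
  # probe the sign linking a placement-dihedral offset about each rotatable
  # bond to the change of its canonical torsion
  axis_sign <- numeric(nrow(rb))
  if (nrow(rb)) {
    t0 <- conformer_torsions(ref, quads)
    for (k in seq_len(nrow(rb))) {
      ics2 <- ics
      hit <- which((ics$plan$records[, 2] == rb[k, 1] &
                    ics$plan$records[, 3] == rb[k, 2]) |
                   (ics$plan$records[, 2] == rb[k, 2] &
                    ics$plan$records[, 3] == rb[k, 1]))
      ics2$dihedrals[hit] <- wrap_angle(ics2$dihedrals[hit] + 10)
      d <- wrap_angle(conformer_torsions(rebuild_cartesian(ics2, g),
                                         quads)[k] - t0[k])
      if (abs(abs(d) - 10) > 1e-6)
        stop("torsion probe failed for bond ", rb[k, 1], "-", rb[k, 2])
      axis_sign[k] <- sign(d)
    }
  }
  structure(list(graph = g, ref = ref, plan = ctx$plan, ics = ics,
                 rot_bonds = rb, axis_sign = axis_sign, quads = quads,
                 kind = kind, seed = seed),
            class = "mol_template")
}

#' @export
print.mol_template <- function(x, ...) {
  cat(sprintf("mol_template (%s): %d atoms, %d rotatable bonds\n",
              x$kind, x$graph$n_atoms, nrow(x$rot_bonds)))
  invisible(x)
}

#' Default torsion mixtures for a template
#'
#' Small-molecule kinds get an anti/gauche mixture on every rotatable bond:
#' mode 180 degrees (weight 0.7) and 60 degrees (weight 0.3).  Peptide-like
#' templates instead emulate a folded ensemble: amide (omega) bonds stay
#' trans (180, sd 3), N-Calpha (phi-like) bonds mix -60/-120, and the
#' remaining bonds mix -45/120/180 — compact helix-leaning structures rather
#' than extended chains.
#'
#' @param template mol_template.
#' @param sd mode standard deviation, degrees (non-amide modes).
#' @return named list of mode tables (bond key "i-j"), as consumed by
#'   \code{\link{sample_ensemble}}.
#' @export
default_torsion_modes <- function(template, sd = 8) {
  rb <- template$rot_bonds
  g <- template$graph
  if (template$kind == "peptide_like") {
    z <- g$atomic_numbers
    nb <- neighbors_list(g)
    has_carbonyl_o <- function(cc) any(vapply(nb[[cc]], function(k) {
      z[k] == 8L && g$bonds[g$bonds[, 1] == min(cc, k) &
                            g$bonds[, 2] == max(cc, k), 3] == 2L
    }, logical(1)))
    classify <- function(i, j) {
      if (z[i] != 7L && z[j] != 7L) return("other")
      cc <- if (z[i] == 7L) j else i
      if (z[cc] == 6L && has_carbonyl_o(cc)) "omega"
      else if (z[cc] == 6L) "phi" else "other"
    }
    modes <- lapply(seq_len(nrow(rb)), function(k)
      switch(classify(rb[k, 1], rb[k, 2]),
        omega = data.frame(mean = 180, sd = 3, weight = 1),
        phi = data.frame(mean = c(-60, -120), sd = sd + 2,
                         weight = c(0.7, 0.3)),
        data.frame(mean = c(-45, 120, 180), sd = sd + 2,
                   weight = c(0.5, 0.3, 0.2))))
  } else {
    modes <- lapply(seq_len(nrow(rb)), function(k)
      data.frame(mean = c(180, 60), sd = sd, weight = c(0.7, 0.3)))
  }
  names(modes) <- paste(rb[, 1], rb[, 2], sep = "-")
  modes
}

#' Sample a conformer ensemble from torsion mixtures
#'
#' Each conformer is drawn by sampling every flagged rotatable-bond torsion
#' from its mixture (setting the canonical torsion of that bond exactly to
#' the drawn value, up to jitter), jittering bond lengths and angles, and
#' rebuilding Cartesian coordinates through the spanning tree.
#'
#' @param template mol_template.
#' @param n_conformers ensemble size.
#' @param torsion_modes named list (bond key "i-j") of data.frames with
#'   columns mean, sd, weight; bonds without an entry keep their reference
#'   torsion (plus jitter).  Default: \code{\link{default_torsion_modes}}.
#' @param bond_jitter Gaussian sd on bond lengths, Angstrom.
#' @param angle_jitter Gaussian sd on bond angles and unflagged dihedrals,
#'   degrees.
#' @param seed integer seed; the ensemble is bitwise reproducible.
#' @return list of conformers.
#' @export
sample_ensemble <- function(template, n_conformers,
                            torsion_modes = default_torsion_modes(template),
                            bond_jitter = 0.01, angle_jitter = 2,
                            seed = 1L) {
  g <- template$graph
  ics0 <- template$ics
  rec <- ics0$plan$records
  n <- nrow(rec)
  rb <- template$rot_bonds
  keys <- paste(rb[, 1], rb[, 2], sep = "-")
  flagged <- which(keys %in% names(torsion_modes))
  for (k in flagged) {
    w <- torsion_modes[[keys[k]]]$weight
    if (abs(sum(w) - 1) > 1e-8) stop("mode weights must sum to 1 (bond ",
                                     keys[k], ")")
    if (any(torsion_modes[[keys[k]]]$sd <= 0)) stop("mode sd must be > 0")
  }
  hits <- lapply(seq_len(nrow(rb)), function(k)
    which((rec[, 2] == rb[k, 1] & rec[, 3] == rb[k, 2]) |
          (rec[, 2] == rb[k, 2] & rec[, 3] == rb[k, 1])))
  t0 <- conformer_torsions(template$ref, template$quads)
  local_seed(seed, {
    lapply(seq_len(n_conformers), function(ci) {
      ics <- ics0
      if (bond_jitter > 0)
        ics$bond_lengths[-1] <- ics$bond_lengths[-1] +
          stats::rnorm(n - 1L, 0, bond_jitter)
      if (angle_jitter > 0) {
        ics$bond_angles[-(1:2)] <- pmin(178, pmax(2,
          ics$bond_angles[-(1:2)] +
            stats::rnorm(n - 2L, 0, angle_jitter)))
        ics$dihedrals[-(1:3)] <- wrap_angle(ics$dihedrals[-(1:3)] +
          stats::rnorm(n - 3L, 0, angle_jitter))
      }
      for (k in flagged) {
        mt <- torsion_modes[[keys[k]]]
        mi <- sample.int(nrow(mt), 1L, prob = mt$weight)
        target <- mt$mean[mi] + stats::rnorm(1L, 0, mt$sd[mi])
        delta <- template$axis_sign[k] * wrap_angle(target - t0[k])
        ics$dihedrals[hits[[k]]] <- wrap_angle(ics$dihedrals[hits[[k]]] +
                                               delta)
      }
      rebuild_cartesian(ics, g)
    })
  })
}

#' Remove the transition region of a bimodal torsion
#'
#' Detects the two dominant modes of the given torsion across the ensemble
#' from a circular kernel density estimate (the two tallest local maxima),
#' then removes every conformer whose torsion lies within \code{band}/2
#' degrees of the midpoint of the shorter arc between the two mode peaks.
#'
#' @param confs list of conformers.
#' @param g molecular_graph.
#' @param quad length-4 atom index vector defining the torsion (or a length-2
#'   rotatable-bond pair, resolved to its canonical quad).
#' @param band full width of the excluded region, degrees (0 < band < 180).
#' @param bw Gaussian kernel bandwidth of the density estimate, degrees.
#' @return list(kept, removed, modes, midpoint).
#' @export
exclude_transition_region <- function(confs, g, quad, band, bw = 15) {
  if (band <= 0 || band >= 180) stop("band must be in (0, 180)")
  if (length(quad) == 2L) {
    quads <- canonical_torsions(g)
    rb <- rotatable_bonds(g)
    k <- which(rb[, 1] == min(quad) & rb[, 2] == max(quad))
    if (!length(k)) stop("not a rotatable bond: ", quad[1], "-", quad[2])
    quad <- quads[k, ]
  }
  tor <- vapply(confs, function(cf)
    dihedral_angle(cf$coords[quad[1], ], cf$coords[quad[2], ],
                   cf$coords[quad[3], ], cf$coords[quad[4], ]), numeric(1))
  grid <- 0:359 - 180
  dens <- vapply(grid, function(gv)
    sum(exp(-0.5 * (wrap_angle(tor - gv) / bw)^2)), numeric(1))
  up <- dens > dens[c(360, 1:359)] & dens >= dens[c(2:360, 1)]
  peaks <- grid[up]
  heights <- dens[up]
  peaks <- peaks[heights >= 0.1 * max(heights)]
  heights <- heights[heights >= 0.1 * max(heights)]
  if (length(peaks) < 2L)
    stop("fewer than 2 torsion modes detected")
  top <- order(heights, decreasing = TRUE)[1:2]
  m1 <- peaks[top[1]]; m2 <- peaks[top[2]]
  midpoint <- wrap_angle(m1 + wrap_angle(m2 - m1) / 2)
  drop <- abs(wrap_angle(tor - midpoint)) < band / 2
  list(kept = confs[!drop], removed = sum(drop),
       modes = c(m1, m2), midpoint = midpoint)
}
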