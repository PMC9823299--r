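# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

ring24 <- function() fixture("ring24", function() {
  tp <- make_template("ring_plus_tail", 13)
  list(tp = tp, ctx = gierc_context(tp$graph))
})

peptide150 <- function() fixture("peptide150", function() {
  tp <- make_template("peptide_like", 75, n_gly = 1, n_ser = 1)
  list(tp = tp, ctx = gierc_context(tp$graph))
})

# a 10-heavy-atom molecule whose atoms are all topologically distinguishable
# (a heteroatom chain without duplicated hydrogens on any heavy atom):
# used for strict elementwise exchange-invariance checks
asym_mol <- function() fixture("asym", function() {
  # O=C(-S-H)-N(-H)-O-C(-F? no F in vocab) ... build: S-C(=O)-N(H)-O-P(=O)(-O-H)
  z <- c(16L, 6L, 8L, 7L, 8L, 15L, 8L, 8L, 1L, 1L, 1L)
  bonds <- rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1), c(4, 5, 1),
                 c(5, 6, 1), c(6, 7, 2), c(6, 8, 1),
                 c(1, 9, 1), c(4, 10, 1), c(8, 11, 1))
  g <- molecular_graph(z, bonds)
  ctx <- gierc_context(g)
  ics <- gierc:::ideal_internal_coords(g, ctx$plan)
  list(g = g, ctx = ctx, ref = rebuild_cartesian(ics, g))
})

# tiny 5-atom branched graph for brute-force permutation checks
tiny_graph <- function(z = c(6L, 7L, 8L, 6L, 1L),
                       bonds = rbind(c(1, 2, 1), c(2, 3, 1), c(2, 4, 1),
                                     c(4, 5, 1))) {
  molecular_graph(z, bonds)
}

# all permutations of 1..n as rows (n small)
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)
    if (pos < n) {
      tmp <- block[, c(seq_len(pos - 1L), n, pos:(n - 1L)), drop = FALSE]
      block <- tmp
    }
    out <- rbind(out, block)
  }
  out
}

# relabel a molecular graph + conformer by permutation perm (new index of
# atom i is perm[i])
relabel <- function(g, conf, perm) {
  inv <- order(perm)
  b <- cbind(perm[g$bonds[, 1]], perm[g$bonds[, 2]], g$bonds[, 3])
  g2 <- molecular_graph(g$atomic_numbers[inv], b,
                        formal_charges = g$formal_charges[inv],
                        chirality = g$chirality_tags[inv],
                        hybridization = g$hybridizations[inv])
  list(g = g2, conf = conformer(conf$coords[inv, , drop = FALSE], g2))
}
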