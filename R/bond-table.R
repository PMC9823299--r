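# Reference bond lengths (Angstrom) keyed by (element pair, formal bond order),
# values taken from published MMFF94 r0 parameters for the common organic
# element set.  The encoder and decoder share this table, so round-trip
# exactness never depends on its absolute accuracy.
.bond_r0 <- local({
  tab <- c(
    "H-H:1"  = 0.742,
    "C-H:1"  = 1.093, "C-C:1" = 1.508, "C-C:2" = 1.333, "C-C:3" = 1.204,
    "C-N:1"  = 1.451, "C-N:2" = 1.273, "C-N:3" = 1.158,
    "C-O:1"  = 1.418, "C-O:2" = 1.222,
    "C-S:1"  = 1.805, "C-S:2" = 1.610,
    "C-P:1"  = 1.810,
    "C-F:1"  = 1.360, "C-Cl:1" = 1.773, "C-Br:1" = 1.949, "C-I:1" = 2.149,
    "H-N:1"  = 1.015, "N-N:1" = 1.381, "N-N:2" = 1.237,
    "N-O:1"  = 1.405, "N-O:2" = 1.208, "N-P:1" = 1.720,
    "H-O:1"  = 0.972, "O-O:1" = 1.450,
    "O-P:1"  = 1.615, "O-P:2" = 1.487, "O-S:1" = 1.670, "O-S:2" = 1.450,
    "H-S:1"  = 1.341, "S-S:1" = 2.051,
    "H-P:1"  = 1.415, "P-P:1" = 2.210,
    "P-S:1"  = 2.120, "P-S:2" = 1.950
  )
  tab
})

# Covalent radii (Angstrom, Cordero et al. consensus values) used as the
# fallback when an (element pair, order) key is absent from the table.
.covalent_radius <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39
)

.element_symbols <- c(
  "1" = "H", "5" = "B", "6" = "C", "7" = "N", "8" = "O", "9" = "F",
  "14" = "Si", "15" = "P", "16" = "S", "17" = "Cl", "35" = "Br", "53" = "I"
)
.element_numbers <- stats::setNames(as.integer(names(.element_symbols)),
                                    .element_symbols)

element_symbol <- function(z) {
  s <- .element_symbols[as.character(z)]
  if (any(is.na(s)))
    stop("unsupported element with atomic number ",
         paste(z[is.na(s)], collapse = ", "))
  unname(s)
}

#' Reference bond length between two elements
#'
#' Looks up the equilibrium bond length for an element pair and formal bond
#' order in an embedded force-field-style table; falls back to the sum of the
#' two covalent radii when the pair/order combination is not tabulated
#' (aromatic order 4 falls back to the mean of the single- and double-bond
#' entries when both exist).
#'
#' @param z_i,z_j atomic numbers of the bonded atoms.
#' @param order formal bond order (1, 2, 3; 4 is treated as aromatic).
#' @return bond length in Angstrom (positive scalar).
#' @export
standard_bond_length <- function(z_i, z_j, order = 1L) {
  si <- element_symbol(z_i)
  sj <- element_symbol(z_j)
  pair <- paste(sort(c(si, sj)), collapse = "-")
  if (order == 4) {
    k1 <- .bond_r0[paste0(pair, ":1")]
    k2 <- .bond_r0[paste0(pair, ":2")]
    if (!is.na(k1) && !is.na(k2)) return(unname((k1 + k2) / 2))
  }
  key <- paste0(pair, ":", as.integer(order))
  r0 <- .bond_r0[key]
  if (!is.na(r0)) return(unname(r0))
  r <- .covalent_radius[si] + .covalent_radius[sj]
  if (is.na(r))
    stop("no covalent radius for element pair ", pair)
  unname(r)
}
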