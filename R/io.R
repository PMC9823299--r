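# Structure file I/O.  SDF (V2000, multi-record) carries connectivity and
# bond orders directly; XYZ and PDB need a sidecar bond table (two or three
# whitespace-separated columns: i, j[, order], 0-based indices).  Multi-
# record files yield conformer ensembles sharing one graph; graph identity
# across records is enforced.

#' Read structures into a molecular graph and conformer list
#'
#' @param path input file.
#' @param format "sdf", "xyz" or "pdb" (default: from the file extension).
#' @param bonds_path sidecar bond table for xyz/pdb (0-based indices,
#'   optional third column bond order).
#' @return list(graph, conformers).
#' @export
read_structures <- function(path, format = NULL, bonds_path = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("sdf", "xyz", "pdb"))
  if (format == "sdf") return(read_sdf(path))
  bonds <- read_bond_table(bonds_path)
  recs <- if (format == "xyz") read_xyz_records(path) else
    read_pdb_records(path)
  z <- .element_numbers[recs$elements[[1]]]
  g <- molecular_graph(z, bonds)
  confs <- lapply(seq_along(recs$coords), function(k) {
    if (!identical(recs$elements[[k]], recs$elements[[1]]))
      stop("record ", k, " has different atoms than record 1")
    conformer(recs$coords[[k]], g)
  })
  list(graph = g, conformers = confs)
}

read_bond_table <- function(bonds_path) {
  if (is.null(bonds_path))
    stop("xyz/pdb input needs a sidecar bond table (bonds_path)")
  tb <- utils::read.table(bonds_path)
  if (ncol(tb) == 2L) tb$order <- 1L
  cbind(tb[[1]] + 1L, tb[[2]] + 1L, as.integer(tb[[3]]))
}

read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF requires the ChemmineR package")
  sdfs <- ChemmineR::read.SDFset(path)
  parse_one <- function(sdf) {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    list(z = .element_numbers[elem], coords = unname(ab[, 1:3]),
         bonds = cbind(bb[, 1], bb[, 2], bb[, 3]))
  }
  first <- parse_one(sdfs[[1]])
  g <- molecular_graph(first$z, first$bonds)
  confs <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    rec <- if (k == 1L) first else parse_one(sdfs[[k]])
    if (!identical(unname(rec$z), unname(first$z)) ||
        !identical(unname(rec$bonds), unname(first$bonds)))
      stop("record ", k, " has a different molecular graph than record 1")
    confs[[k]] <- conformer(rec$coords, g)
  }
  list(graph = g, conformers = confs)
}

read_xyz_records <- function(path) {
  lines <- readLines(path)
  coords <- list(); elements <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    elements[[length(elements) + 1L]] <- vapply(tok, `[`, "", 1L)
    coords[[length(coords) + 1L]] <-
      t(vapply(tok, function(tt) as.numeric(tt[2:4]), numeric(3)))
    i <- i + 2L + n
  }
  list(coords = coords, elements = elements)
}

read_pdb_records <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  el <- trimws(pdb$atom$elesy)
  if (!all(nzchar(el))) el <- toupper(substr(trimws(pdb$atom$elety), 1, 1))
  el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
  nmod <- dim(pdb$xyz)[1]
  coords <- lapply(seq_len(nmod), function(k)
    matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE))
  list(coords = coords, elements = rep(list(el), nmod))
}

#' Write conformers to a structure file
#'
#' SDF output is multi-record V2000 with the shared connectivity repeated per
#' record; XYZ output is plain multi-frame XYZ.  Output bytes are a
#' deterministic function of the inputs.
#'
#' @param confs list of conformers (or a single conformer).
#' @param path output file.
#' @param format "sdf" or "xyz" (default from extension).
#' @param names record names (default "mol_1", "mol_2", ...).
#' @return invisibly, the path.
#' @export
write_structures <- function(confs, path, format = NULL, names = NULL) {
  if (inherits(confs, "conformer")) confs <- list(confs)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("sdf", "xyz"))
  if (is.null(names)) names <- paste0("mol_", seq_along(confs))
  g <- confs[[1]]$graph
  sym <- element_symbol(g$atomic_numbers)
  out <- character(0)
  for (k in seq_along(confs)) {
    x <- confs[[k]]$coords
    if (format == "sdf") {
      out <- c(out, names[k], "  gierc", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       g$n_atoms, nrow(g$bonds)),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       x[, 1], x[, 2], x[, 3], sym),
               sprintf("%3d%3d%3d  0", g$bonds[, 1], g$bonds[, 2],
                       g$bonds[, 3]),
               "M  END", "$$$$")
    } else {
      out <- c(out, as.character(g$n_atoms), names[k],
               sprintf("%-3s %12.6f %12.6f %12.6f", sym,
                       x[, 1], x[, 2], x[, 3]))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Serialize a GIE-RC encoding to a JSON container
#'
#' Single JSON document: a header (graph fingerprint, canonical order,
#' padding width, cutoffs) plus the flattened feature tensor at full double
#' precision.
#'
#' @param f giercm object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_giercm <- function(f, path) {
  obj <- list(container = "giercm", version = 1L,
              fingerprint = f$fingerprint, order = f$order, m = f$m,
              rcs = f$rcs, rc = f$rc, dim = dim(f$features),
              features = as.numeric(f$features))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GIE-RC encoding from its JSON container
#' @param path file written by \code{\link{write_giercm}}.
#' @return giercm object.
#' @export
read_giercm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "giercm")) stop("not a giercm container")
  structure(list(features = array(obj$features, obj$dim), m = obj$m,
                 order = obj$order, rcs = obj$rcs, rc = obj$rc,
                 fingerprint = obj$fingerprint), class = "giercm")
}

#' Default run configuration
#'
#' Bundles the tunables shared by the command-line tools: attenuation
#' cutoffs (5.0 / 6.0 Angstrom), consensus DBSCAN radii (0.1 Angstrom, 20
#' degrees, 20 degrees), latent dimension 128 and 5 percent latent noise.
#'
#' @param ... overrides of the named defaults.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(rcs = 5.0, rc = 6.0, eps_bond = 0.1, eps_angle = 20,
              eps_dihedral = 20, latent_dim = 128L, noise_percent = 0.05,
              seed = 1L)
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!(cfg$rcs < cfg$rc)) stop("need rcs < rc")
  structure(cfg, class = "run_config")
}
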