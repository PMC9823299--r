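#' Flatten a conformer into one of three representations
#'
#' \code{gie_rc}: the flattened GIE-RC tensor; \code{internal}: the flattened
#' spanning-tree Z-matrix (Angstrom, degrees, degrees); \code{cartesian}:
#' flattened centroid-centered coordinates.  The returned object carries the
#' metadata needed to invert the flattening.
#'
#' @param conf conformer.
#' @param kind one of "gie_rc", "internal", "cartesian".
#' @param ctx optional codec context.
#' @return object of class \code{representation}: list(kind, values, meta).
#' @export
to_representation <- function(conf, kind = c("gie_rc", "internal",
                                             "cartesian"), ctx = NULL) {
  kind <- match.arg(kind)
  if (is.null(ctx)) ctx <- gierc_context(conf$graph)
  v <- switch(kind,
    gie_rc = {
      f <- gierc_encode(conf, ctx = ctx)
      list(values = as.numeric(f$features), meta = f)
    },
    internal = {
      ics <- measure_internal_coords(conf, ctx$plan)
      vals <- c(ics$bond_lengths, ics$bond_angles, ics$dihedrals)
      list(values = vals[!is.na(vals)], meta = ics)
    },
    cartesian = {
      centered <- sweep(conf$coords, 2, colMeans(conf$coords))
      list(values = as.numeric(centered), meta = list(n = nrow(conf$coords)))
    })
  structure(list(kind = kind, values = v$values, meta = v$meta,
                 graph = conf$graph, ctx_rcs = ctx$rcs, ctx_rc = ctx$rc),
            class = "representation")
}

#' Decode a (possibly perturbed) representation back to a conformer
#'
#' The internal-coordinate baseline decodes through the same sequential
#' rebuild as GIE-RC, isolating the representation (not the rebuilder) as
#' the variable under test.
#'
#' @param rep representation object.
#' @param ctx optional codec context.
#' @return conformer.
#' @export
from_representation <- function(rep, ctx = NULL) {
  g <- rep$graph
  if (is.null(ctx)) ctx <- gierc_context(g, rep$ctx_rcs, rep$ctx_rc)
  switch(rep$kind,
    gie_rc = {
      f <- rep$meta
      f$features <- array(rep$values, dim(f$features))
      gierc_decode(f, ctx = ctx)
    },
    internal = {
      ics <- rep$meta
      n <- length(ics$bond_lengths)
      nb <- n - 1L; na <- n - 2L; nd <- n - 3L
      ics$bond_lengths[-1] <- rep$values[seq_len(nb)]
      ics$bond_angles[-(1:2)] <- rep$values[nb + seq_len(na)]
      ics$dihedrals[-(1:3)] <- wrap_angle(rep$values[nb + na + seq_len(nd)])
      rebuild_cartesian(ics, g)
    },
    cartesian = conformer(matrix(rep$values, ncol = 3L), g, check = FALSE))
}

#' Impose percentage noise on a representation
#'
#' Elementwise multiplicative Gaussian perturbation x -> x (1 + p e) with e
#' standard normal; exact zeros (padding) are left untouched, so the tensor
#' structure is preserved.  With p = 0 the input is returned bit-identically.
#'
#' @param rep representation (or bare numeric vector).
#' @param percent noise fraction p (e.g. 0.05 for 5 percent).
#' @param seed integer seed; the perturbation is reproducible.
#' @return perturbed object of the same type.
#' @export
add_percentage_noise <- function(rep, percent, seed = NULL) {
  vals <- if (inherits(rep, "representation")) rep$values else rep
  if (percent > 0) {
    noisy <- local_seed(seed, {
      nz <- vals != 0
      v <- vals
      v[nz] <- vals[nz] * (1 + percent * stats::rnorm(sum(nz)))
      v
    })
    vals <- noisy
  }
  if (inherits(rep, "representation")) { rep$values <- vals; rep } else vals
}

# evaluate expr under a temporary RNG state seeded by `seed` (global RNG
# state is saved and restored); seed NULL uses the current RNG stream
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Noise-robustness benchmark over the three representations
#'
#' For each noise level and representation: flatten each conformer, impose
#' multiplicative percentage noise, decode back to Cartesian coordinates and
#' measure coordinate RMSD (after optimal superposition) and torsion RMSD
#' against the original; entries are means over \code{n_pairs} structures and
#' \code{repeats} noise draws.
#'
#' @param confs list of conformers (>= n_pairs).
#' @param g molecular_graph.
#' @param levels noise percents, e.g. \code{c(0, 2.5, 5, 10)} (percent units).
#' @param n_pairs structures per cell (default 10).
#' @param seed integer; all noise draws derive from it.
#' @param repeats independent noise repetitions averaged per cell.
#' @param kinds representations to include.
#' @param system label copied into the report.
#' @return data.frame: system, n_atoms, level, kind, rmsd, torsion_rmsd,
#'   n_pairs, repeats.
#' @export
run_noise_benchmark <- function(confs, g, levels = c(0, 2.5, 5, 10),
                                n_pairs = 10L, seed = 1L, repeats = 1L,
                                kinds = c("gie_rc", "internal", "cartesian"),
                                system = "synthetic") {
  if (length(confs) < n_pairs) stop("need at least n_pairs conformers")
  ctx <- gierc_context(g)
  quads <- canonical_torsions(g, ctx$s)
  confs <- confs[seq_len(n_pairs)]
  torsions0 <- lapply(confs, conformer_torsions, quads = quads)
  reps <- lapply(kinds, function(k)
    lapply(confs, to_representation, kind = k, ctx = ctx))
  names(reps) <- kinds
  out <- expand.grid(system = system, n_atoms = g$n_atoms, level = levels,
                     kind = kinds, stringsAsFactors = FALSE)
  out$rmsd <- NA_real_; out$torsion_rmsd <- NA_real_
  out$n_pairs <- n_pairs; out$repeats <- repeats
  for (row in seq_len(nrow(out))) {
    lev <- out$level[row]; kind <- out$kind[row]
    acc_r <- acc_t <- 0
    for (rep_i in seq_len(repeats)) {
      for (ci in seq_len(n_pairs)) {
        sd_i <- seed + 7919L * rep_i + 104729L * ci +
          1299709L * match(lev, levels)
        noisy <- add_percentage_noise(reps[[kind]][[ci]], lev / 100, sd_i)
        dec <- from_representation(noisy, ctx = ctx)
        acc_r <- acc_r + kabsch_rmsd(confs[[ci]], dec)
        dt <- wrap_angle(conformer_torsions(dec, quads) - torsions0[[ci]])
        acc_t <- acc_t + sqrt(mean(dt^2))
      }
    }
    out$rmsd[row] <- acc_r / (repeats * n_pairs)
    out$torsion_rmsd[row] <- acc_t / (repeats * n_pairs)
  }
  out
}
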