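# Vector and angle kernels.  Angles are degrees at the API surface, radians
# only inside these functions.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  a / n
}

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180

#' Wrap angles to [-180, 180)
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) ((x + 180) %% 360) - 180

#' Circular mean of angles
#' @param x angles in degrees.
#' @return mean direction in degrees, wrapped to [-180, 180).
#' @export
circular_mean <- function(x) {
  wrap_angle(deg(atan2(mean(sin(rad(x))), mean(cos(rad(x))))))
}

# 3-point bond angle at p2, degrees in (0, 180)
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  co <- sum(u * v) / (vnorm(u) * vnorm(v))
  deg(acos(max(-1, min(1, co))))
}

# signed proper dihedral p1-p2-p3-p4, degrees in [-180, 180)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  wrap_angle(deg(atan2(sum(m1 * n2), sum(n1 * n2))))
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' All-atom root-mean-square deviation after optimal rigid superposition of
#' \code{b} onto \code{a} using the closed-form SVD solution restricted to
#' proper rotations.
#'
#' @param a,b conformers (or N x 3 coordinate matrices) with identical atom
#'   count and order.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  xa <- if (inherits(a, "conformer")) a$coords else a
  xb <- if (inherits(b, "conformer")) b$coords else b
  if (!all(dim(xa) == dim(xb))) stop("atom count mismatch")
  xa <- sweep(xa, 2, colMeans(xa))
  xb <- sweep(xb, 2, colMeans(xb))
  h <- crossprod(xb, xa)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diffs <- xa - xb %*% t(r)
  sqrt(mean(rowSums(diffs^2)))
}

#' Torsion RMSD between two conformers
#'
#' Root-mean-square of circularly wrapped differences over the canonical
#' torsion set (one proper dihedral per rotatable non-terminal bond, flanking
#' atoms chosen by canonical rank).
#'
#' @param a,b conformers sharing the same molecular graph.
#' @param g molecular_graph; defaults to the graph bound to \code{a}.
#' @return RMSD in degrees.
#' @export
torsion_rmsd <- function(a, b, g = NULL) {
  if (is.null(g)) g <- a$graph
  quads <- canonical_torsions(g)
  ta <- conformer_torsions(a, quads)
  tb <- conformer_torsions(b, quads)
  sqrt(mean(wrap_angle(ta - tb)^2))
}

# dihedral values (degrees) of a conformer over a quad matrix
conformer_torsions <- function(conf, quads) {
  x <- if (inherits(conf, "conformer")) conf$coords else conf
  vapply(seq_len(nrow(quads)), function(k) {
    q <- quads[k, ]
    dihedral_angle(x[q[1], ], x[q[2], ], x[q[3], ], x[q[4], ])
  }, numeric(1))
}

# apply a uniformly random proper rotation + translation (for invariance tests)
random_rigid_motion <- function(coords) {
  q <- stats::rnorm(4); q <- q / vnorm(q)
  r <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
  t_vec <- stats::rnorm(3, sd = 10)
  sweep(coords %*% t(r), 2, t_vec, "+")
}
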