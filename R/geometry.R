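# Low-level 3D geometry: vector helpers, internal-coordinate atom placement
# (natural-extension reference frame), dihedrals, and Kabsch superposition.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Bond angle at `b` (degrees) formed by points a-b-c
#' @param a,b,c numeric 3-vectors (coordinates in Angstrom).
#' @return Angle in degrees in \[0, 180\].
#' @export
bond_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle (degrees) defined by four points
#'
#' Signed torsion a-b-c-d using the standard IUPAC convention
#' (positive = clockwise looking from b towards c). Satisfies
#' `dihedral(a,b,c,d) == dihedral(d,c,b,a)`.
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame (NeRF) construction: returns the position
#' `d` such that `|d - c| == bond`, the angle d-c-b equals `angle` and the
#' torsion a-b-c-d equals `torsion`.
#'
#' @param a,b,c numeric 3-vectors, the three reference atoms (`c` is the atom
#'   the new atom bonds to).
#' @param bond bond length in Angstrom.
#' @param angle bond angle d-c-b in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return numeric 3-vector, the new position.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), -bond * sin(ang) * sin(tor))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1; reflections excluded) and
#' translation that minimize the RMSD of `coords_b` onto `coords_a`.
#'
#' @param coords_a,coords_b numeric matrices of matching dimension (n x 3),
#'   n >= 3, rows are points.
#' @return A list with `rotation` (3x3, det +1), `translation` (3-vector),
#'   `rmsd` (Angstrom). Applying `sweep(coords_b %*% t(rotation), 2,
#'   translation, "+")` gives the superposed copy of `coords_b`.
#' @export
superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)) || ncol(coords_a) != 3)
    stop("coordinate sets must be matching n x 3 matrices")
  if (nrow(coords_a) < 3)
    stop("need at least 3 points for superposition")
  if (!all(is.finite(coords_a)) || !all(is.finite(coords_b)))
    stop("coordinates must be finite")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rotated <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((rotated - A)^2)))
  list(rotation = R,
       translation = as.numeric(ca - (cb %*% t(R))),
       rmsd = rmsd)
}

#' RMSD after optimal superposition
#'
#' Convenience wrapper around [superpose()] returning just the minimal RMSD.
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(coords_a, coords_b) {
  superpose(coords_a, coords_b)$rmsd
}

# RMSD without superposition (used internally for fixed-frame checks).
raw_rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
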