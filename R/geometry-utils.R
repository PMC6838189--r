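# Small 3D geometry toolkit used throughout the package.  All coordinates are
# in Angstrom, all angles in degrees unless a name says otherwise.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex b of the triple a-b-c
#'
#' @param a,b,c numeric 3-vectors.
#' @return angle in degrees in \[0, 180\].
#' @keywords internal
angle3 <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: the cis (eclipsed) arrangement is 0 degrees and a
#' clockwise rotation of d relative to a, viewed down b->c, is positive.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return torsion in degrees in (-180, 180\].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("coincident atoms in torsion")
  c12 <- cross3(b1, b2)
  c23 <- cross3(b2, b3)
  y <- vnorm(b2) * sum(b1 * c23)
  x <- sum(c12 * c23)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric 3-vector (need not be normalized).
#' @param theta angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rot_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

rot_z <- function(theta) rot_about_axis(c(0, 0, 1), theta)
rot_y <- function(theta) rot_about_axis(c(0, 1, 0), theta)
rot_x <- function(theta) rot_about_axis(c(1, 0, 0), theta)

#' Place an atom from internal coordinates (natural extension reference frame)
#'
#' Given three placed atoms a-b-c, returns the position of a new atom d bonded
#' to c such that |c-d| = bond, angle(b,c,d) = angle and dihedral(a,b,c,d) =
#' torsion.
#'
#' @param a,b,c numeric 3-vectors of already-placed atoms.
#' @param bond bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return numeric 3-vector.
#' @keywords internal
nerf_place <- function(a, b, c, bond, angle, torsion) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  ang <- deg2rad(180 - angle)   # polar angle from the extension of b->c
  tor <- deg2rad(torsion)
  d_local <- bond * c(cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  # basis: bc, m, n  (so that torsion follows the IUPAC sign of dihedral())
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Fill remaining tetrahedral positions at center x with already-bonded
# neighbours nb (matrix, one row per neighbour).  Returns `n_new` unit
# directions completing an approximately tetrahedral arrangement.
tetra_fill <- function(x, nb, n_new = 1, pair_angle = 109.47) {
  nb <- rbind(nb)
  dirs <- t(apply(nb, 1, function(p) unitv(p - x)))
  bis <- -colSums(dirs)
  if (vnorm(bis) < 1e-8) stop("degenerate neighbour arrangement")
  bis <- unitv(bis)
  if (n_new == 1) return(rbind(bis))
  if (nrow(dirs) != 2 || n_new != 2)
    stop("tetra_fill supports 1 new direction, or 2 new with 2 neighbours")
  axis <- unitv(cross3(dirs[1, ], dirs[2, ]))
  half <- pair_angle / 2
  rbind(c(rot_about_axis(cross3(axis, bis), half) %*% bis),
        c(rot_about_axis(cross3(axis, bis), -half) %*% bis))
}

# Wrap an angle into [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Signed smallest difference between two angles in degrees, in (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
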