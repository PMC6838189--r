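# Rigid-body base-pair and base-pair-step parameters.
#
# Convention (one fixed published scheme): a standard reference frame is
# least-squares fitted to the ring atoms of each base; the strand-2 frame
# is flipped (y, z negated) to account for the antiparallel strand.  The
# two frames are then symmetrically hinged onto a common z axis, the
# mid-frame is formed, and the six rigid-body parameters are read off:
# rotation about the mid-frame x axis (buckle / tilt), y axis (propeller /
# roll), z axis (opening / twist), and the mid-frame components of the
# origin displacement (shear, stretch, stagger / shift, slide, rise).
# Different published tools differ by small systematic offsets in these
# parameters; within-package comparisons are exact.

signed_angle <- function(a, b, axis) {
  rad2deg(atan2(sum(cross3(a, b) * axis), sum(a * b)))
}

#' Fit the standard base frame to one residue
#'
#' @param frame a classified \code{conformation_frame}.
#' @param residue residue index.
#' @param flip TRUE for strand-2 bases (y and z axes negated after the
#'   fit).
#' @return list with \code{R} (columns = frame axes), \code{origin},
#'   \code{fit_rmsd} and \code{flag} ("distorted" above 0.5 A).
#' @export
fit_base_frame <- function(frame, residue, flip = FALSE) {
  code <- frame$atoms$residue_code[frame$atoms$residue_index == residue][1]
  tpl <- get_template(code)
  obs <- t(vapply(tpl$ring, function(a) atom_xyz(frame, residue, a),
                  numeric(3)))
  sp <- superpose(tpl$coords[tpl$ring, , drop = FALSE], obs)
  R <- sp$rotation
  origin <- as.vector(sp$translation)  # image of the standard-frame origin
  if (flip) R <- R %*% diag(c(1, -1, -1))
  list(R = R, origin = origin, fit_rmsd = sp$rmsd,
       flag = if (sp$rmsd > 0.5) "distorted" else "")
}

# CEHS-style six parameters between two frames (R1,o1) -> (R2,o2).
rigid_params <- function(R1, o1, R2, o2) {
  z1 <- R1[, 3]; z2 <- R2[, 3]
  gamma <- angle3(o1 + z1, o1, o1 + z2)
  hinge <- cross3(z1, z2)
  if (vnorm(hinge) < 1e-9) hinge <- R1[, 2]
  R1p <- rot_about_axis(hinge, gamma / 2) %*% R1
  R2p <- rot_about_axis(hinge, -gamma / 2) %*% R2
  zm <- unitv((R1p[, 3] + R2p[, 3]) / 2)
  twist <- signed_angle(R1p[, 1], R2p[, 1], zm)
  xm <- unitv(R1p[, 1] + R2p[, 1])
  ym <- cross3(zm, xm)
  Rm <- cbind(xm, ym, zm)
  phi <- signed_angle(unitv(hinge), ym, zm)
  roll <- gamma * cos(deg2rad(phi))
  tilt <- gamma * sin(deg2rad(phi))
  tr <- as.vector(crossprod(Rm, o2 - o1))
  list(Rm = Rm, om = (o1 + o2) / 2,
       rot = c(tilt = tilt, roll = roll, twist = twist),
       tr = c(x = tr[1], y = tr[2], z = tr[3]))
}

#' Base-pair parameters of pair i
#'
#' @param frame a classified \code{conformation_frame}.
#' @param topo the \code{duplex_topology}.
#' @param i pair index (1..N).
#' @return list with \code{shear}, \code{stretch}, \code{stagger} (A),
#'   \code{buckle}, \code{propeller}, \code{opening} (deg), \code{c1c1}
#'   (A), the pair mid-frame (\code{Rm}, \code{om}) and base-fit RMSDs.
#' @export
base_pair_params <- function(frame, topo, i) {
  f1 <- fit_base_frame(frame, i)
  f2 <- fit_base_frame(frame, topo$pairing[i], flip = TRUE)
  # parameters from the strand-2 base towards the strand-1 base
  p <- rigid_params(f2$R, f2$origin, f1$R, f1$origin)
  c1c1 <- vnorm(atom_xyz(frame, i, "C1'") -
                atom_xyz(frame, topo$pairing[i], "C1'"))
  list(shear = unname(p$tr["x"]), stretch = unname(p$tr["y"]),
       stagger = unname(p$tr["z"]),
       buckle = unname(p$rot["tilt"]), propeller = unname(p$rot["roll"]),
       opening = unname(p$rot["twist"]),
       c1c1 = c1c1, Rm = p$Rm, om = p$om,
       fit_rmsd = c(f1$fit_rmsd, f2$fit_rmsd),
       flag = paste0(f1$flag, f2$flag))
}

#' Base-pair step parameters between pairs i and i+1
#'
#' @inheritParams base_pair_params
#' @param i step index (1..N-1).
#' @return list with \code{shift}, \code{slide}, \code{rise} (A),
#'   \code{tilt}, \code{roll}, \code{twist} (deg).
#' @export
step_params <- function(frame, topo, i) {
  p1 <- base_pair_params(frame, topo, i)
  p2 <- base_pair_params(frame, topo, i + 1)
  p <- rigid_params(p1$Rm, p1$om, p2$Rm, p2$om)
  list(shift = unname(p$tr["x"]), slide = unname(p$tr["y"]),
       rise = unname(p$tr["z"]),
       tilt = unname(p$rot["tilt"]), roll = unname(p$rot["roll"]),
       twist = unname(p$rot["twist"]))
}

#' Helical twist and rise measured from pair origins
#'
#' Complementary to the local step parameters: fits the global helix from
#' the fitted pair mid-frame origins — rise as the mean successive origin
#' displacement along the mean advance direction, twist as the mean
#' rotation of the radial component about it.  For an ideal screw-placed
#' duplex these recover the construction parameters exactly.
#'
#' @param frame a classified \code{conformation_frame}.
#' @param topo the \code{duplex_topology}.
#' @return list with \code{rise} (A) and \code{twist} (deg).
#' @export
helical_parameters <- function(frame, topo) {
  oms <- t(vapply(seq_len(topo$N), function(i)
    base_pair_params(frame, topo, i)$om, numeric(3)))
  dif <- diff(oms)
  if (nrow(dif) >= 3) {
    # the advance along the screw axis is constant, so the axis is the
    # minimum-variance direction of the chord vectors
    ev <- eigen(stats::cov(dif), symmetric = TRUE)
    axis <- ev$vectors[, 3]
  } else {
    # too few chords: fall back on the mean base-pair normal
    zs <- t(vapply(seq_len(topo$N), function(i)
      base_pair_params(frame, topo, i)$Rm[, 3], numeric(3)))
    axis <- unitv(colMeans(zs))
  }
  if (sum(dif %*% axis) < 0) axis <- -axis
  rises <- as.vector(dif %*% axis)
  # in-plane circle fit (Kasa) locates the helix axis among the origins
  e1 <- unitv(cross3(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- cross3(axis, e1)
  px <- as.vector(oms %*% e1)
  py <- as.vector(oms %*% e2)
  A <- cbind(2 * px, 2 * py, 1)
  sol <- qr.solve(A, px^2 + py^2)
  radial <- cbind(px - sol[1], py - sol[2])
  tw <- vapply(seq_len(nrow(radial) - 1), function(k)
    signed_angle(c(radial[k, ], 0), c(radial[k + 1, ], 0), c(0, 0, 1)), 0)
  list(rise = mean(rises), twist = mean(abs(tw)))
}
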