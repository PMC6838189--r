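# Torsion angles, glycosidic chi, sugar pseudorotation and distance series.

#' Torsion angle between four named atoms
#'
#' @param frame a \code{conformation_frame}.
#' @param spec list of four \code{c(residue_index, atom_name)} pairs, or a
#'   4 x 2 matrix-like of (residue, name).
#' @return torsion in degrees, IUPAC convention, in (-180, 180\].
#' @export
frame_torsion <- function(frame, spec) {
  if (length(spec) != 4) stop("need exactly four atoms")
  p <- lapply(spec, function(s)
    atom_xyz(frame, as.integer(s[[1]]), as.character(s[[2]])))
  dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' Glycosidic torsion chi of a residue
#'
#' chi is O4'-C1'-N1-C2 for pyrimidines, O4'-C1'-N9-C4 for purines, and the
#' C-glycoside analogue O4'-C1'-C5-C4 for pseudouridine.  Reported in
#' \[0, 360) so that the anti range reads as ~170-280 degrees.
#'
#' @param frame a classified \code{conformation_frame}.
#' @param residue residue index.
#' @return chi in degrees in \[0, 360).
#' @export
glycosidic_chi <- function(frame, residue) {
  code <- frame$atoms$residue_code[frame$atoms$residue_index == residue][1]
  atoms <- switch(code,
    A = , G = c("N9", "C4"),
    C = , U = c("N1", "C2"),
    PSU = c("C5", "C4"),
    stop("no glycosidic torsion for residue code ", code))
  wrap360(frame_torsion(frame, list(
    c(residue, "O4'"), c(residue, "C1'"),
    c(residue, atoms[1]), c(residue, atoms[2]))))
}

#' Sugar pseudorotation phase and amplitude
#'
#' Computes the five endocyclic torsions nu0..nu4 of the ribose and the
#' pseudorotation phase P and amplitude tau_m from the Altona-Sundaralingam
#' relation
#'   tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72)),
#'   tau_m = nu2 / cos P,
#' with the quadrant resolved so that C3'-endo sugars give P in \[0, 36).
#' When nu2 is close to zero (P near 90 or 270 deg) the amplitude is taken
#' from nu0 instead and the result is flagged.
#'
#' @param frame a \code{conformation_frame}.
#' @param residue residue index.
#' @return object of class \code{sugar_pucker}: list with \code{nu}
#'   (5 torsions, deg), \code{phase} (deg, \[0, 360)), \code{amplitude}
#'   (deg) and \code{flag}.
#' @export
pseudorotation <- function(frame, residue) {
  g <- function(a) atom_xyz(frame, residue, a)
  quads <- list(c("C4'", "O4'", "C1'", "C2'"),
                c("O4'", "C1'", "C2'", "C3'"),
                c("C1'", "C2'", "C3'", "C4'"),
                c("C2'", "C3'", "C4'", "O4'"),
                c("C3'", "C4'", "O4'", "C1'"))
  nu <- vapply(quads, function(q) dihedral(g(q[1]), g(q[2]), g(q[3]), g(q[4])), 0)
  denom <- 2 * nu[3] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  flag <- ""
  if (abs(nu[3]) < 1e-3) {
    # nu2 ~ 0: phase is +-90 deg; use nu0 for the amplitude
    P <- if (num > 0) 90 else 270
    taum <- abs(nu[1] / cos(deg2rad(P + 144 * (0 - 2))))
    flag <- "nu2-degenerate"
  } else {
    P <- rad2deg(atan2(num, denom))
    # atan2 resolves the quadrant: cos P and nu2 share their sign
    if (nu[3] < 0 && cos(deg2rad(P)) > 0) P <- P + 180
    P <- wrap360(P)
    taum <- nu[3] / cos(deg2rad(P))
  }
  structure(list(nu = nu, phase = P, amplitude = taum, flag = flag),
            class = "sugar_pucker")
}

#' @export
print.sugar_pucker <- function(x, ...) {
  cat(sprintf("sugar pucker: P = %.1f deg, tau_m = %.1f deg%s\n",
              x$phase, x$amplitude,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Interatomic distance series over a trajectory
#'
#' @param traj a \code{trajectory}.
#' @param spec_i,spec_j atom specifications \code{c(residue_index, name)}.
#' @return list with \code{distances} (per frame, Angstrom), \code{mean},
#'   \code{sd}.
#' @export
distance_series <- function(traj, spec_i, spec_j) {
  fr1 <- traj$frames[[1]]
  i <- atom_index(fr1, as.integer(spec_i[[1]]), as.character(spec_i[[2]]))
  j <- atom_index(fr1, as.integer(spec_j[[1]]), as.character(spec_j[[2]]))
  d <- vapply(traj$frames, function(fr) {
    m <- frame_coords(fr)
    vnorm(m[i, ] - m[j, ])
  }, 0)
  list(distances = d, mean = mean(d), sd = stats::sd(d))
}

#' Mean C1'-C1' distance across Watson-Crick pairs
#'
#' @param frame a \code{conformation_frame}.
#' @param topo the matching \code{duplex_topology}.
#' @return list with per-pair distances and their mean (Angstrom).
#' @export
c1c1_distances <- function(frame, topo) {
  d <- vapply(seq_len(topo$N), function(i)
    vnorm(atom_xyz(frame, i, "C1'") -
          atom_xyz(frame, topo$pairing[i], "C1'")), 0)
  list(per_pair = d, mean = mean(d))
}
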