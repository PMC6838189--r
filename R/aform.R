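# Idealized A-form duplex construction.
#
# Each base pair is assembled in the standard pair frame from the base
# templates (strand-2 base rotated 180 deg about x), the ribose and
# phosphodiester backbone are attached per nucleotide from internal
# coordinates (sugar pucker from the pseudorotation model, canonical A-form
# backbone torsions), and pair i is placed by the helical screw
#   r_global = Rz((i-1) * twist) %*% (Ry(inclination) %*% r + (x_disp, 0, 0))
#              + (0, 0, (i-1) * rise).
# The 5'-terminal residue of each strand has no phosphate group.

#' A-form helix construction parameters
#'
#' Defaults describe a classic A-RNA fiber geometry: helical twist 32.7
#' deg/bp and rise 2.81 A/bp with the deep-groove base-pair displacement of
#' -4.4 A.  Base-pair inclination defaults to 0 so the helix axis is normal
#' to the base planes; this keeps the local stacking geometry identical at
#' every step (see the vignette for why the tilted-pair variant is not the
#' default).
#' Sugars are C3'-endo; the pseudorotation defaults (phase 11 deg, amplitude
#' 42 deg) match the values typical of well-refined A-RNA solution
#' structures.  Glycosidic torsions are anti: chi defaults to 205 deg for the
#' standard residues and 195 deg for pseudouridine, the ~10 deg lower-anti
#' shift characteristic of the C-glycoside.
#'
#' @param twist helical twist per base pair, degrees.
#' @param rise helical rise per base pair, Angstrom.
#' @param x_disp displacement of the pair centre from the helix axis, A.
#' @param inclination base-pair inclination, degrees.
#' @param pucker_phase,pucker_amplitude sugar pseudorotation phase and
#'   amplitude, degrees.  The phase must describe a C3'-endo sugar
#'   (phase in \[0, 36)).
#' @param chi_anti glycosidic torsion (deg, reported in \[0, 360)) for
#'   A, U, G and C residues.
#' @param chi_psu glycosidic torsion for pseudouridine.
#' @return object of class \code{aform_parameters} (a named list).
#' @export
aform_parameters <- function(twist = 32.7, rise = 2.81,
                             x_disp = -4.4, inclination = 0,
                             pucker_phase = 11, pucker_amplitude = 42,
                             chi_anti = 205, chi_psu = 195) {
  if (pucker_phase < 0 || pucker_phase >= 36)
    stop("pucker_phase must lie in [0, 36) degrees (C3'-endo)")
  structure(list(twist = twist, rise = rise, x_disp = x_disp,
                 inclination = inclination,
                 pucker_phase = pucker_phase,
                 pucker_amplitude = pucker_amplitude,
                 chi_anti = chi_anti, chi_psu = chi_psu),
            class = "aform_parameters")
}

# Endocyclic torsion targets nu_0..nu_4 from phase P and amplitude tau_m
pseudorotation_torsions <- function(P, taum) {
  j <- 0:4
  taum * cos(deg2rad(P + 144 * (j - 2)))
}

# Furanose ring coordinates (C1', C2', C3', C4', O4') with the requested
# pseudorotation state, found by a small deterministic least-squares fit of
# the five ring bonds and five endocyclic torsions.
ribose_ring <- function(P, taum) {
  bonds <- c(1.526, 1.525, 1.523, 1.451, 1.414) # C1-C2,C2-C3,C3-C4,C4-O4,O4-C1
  nu_t <- pseudorotation_torsions(P, taum)
  # start: planar pentagon + Cremer-Pople-style out-of-plane displacement
  start_ring <- function(phi) {
    th <- 2 * pi * (0:4) / 5
    r <- 1.25
    cbind(r * cos(th), r * sin(th),
          sqrt(2 / 5) * 0.38 * cos(2 * th + phi))
  }
  ring_resid <- function(x) {
    m <- matrix(x, 5, 3)
    idx <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))
    db <- vapply(1:5, function(k) vnorm(m[idx[k, 2], ] - m[idx[k, 1], ]), 0) - bonds
    # nu_0: C4'-O4'-C1'-C2' etc., with ring rows (C1',C2',C3',C4',O4')
    quads <- rbind(c(4, 5, 1, 2), c(5, 1, 2, 3), c(1, 2, 3, 4),
                   c(2, 3, 4, 5), c(3, 4, 5, 1))
    dt <- vapply(1:5, function(k)
      angle_diff(dihedral(m[quads[k, 1], ], m[quads[k, 2], ],
                          m[quads[k, 3], ], m[quads[k, 4], ]), nu_t[k]), 0)
    sum((10 * db)^2) + sum(deg2rad(dt)^2)
  }
  best <- NULL
  for (phi in seq(0, 2 * pi, length.out = 13)[-13]) {
    o <- stats::optim(as.vector(start_ring(phi)), ring_resid,
                      method = "BFGS",
                      control = list(maxit = 400, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value > 1e-4)
    warning("ribose ring closure residual larger than expected")
  m <- matrix(best$par, 5, 3)
  rownames(m) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  m
}

.ring_cache <- new.env(parent = emptyenv())
ribose_ring_cached <- function(P, taum) {
  key <- sprintf("%.4f_%.4f", P, taum)
  if (is.null(.ring_cache[[key]])) .ring_cache[[key]] <- ribose_ring(P, taum)
  .ring_cache[[key]]
}

# Rigid transform (R, t) mapping points so that `from` maps onto `to`
# exactly for the first point and in a least-squares sense for the rest.
# Here used only with exact constructions; see superpose() for fitting.

# Attach sugar and backbone to a placed base.  `base_xyz` is the placed base
# template (named matrix), code its residue code.  Returns a named matrix of
# the sugar/backbone atoms (and H1').  Canonical A-form backbone torsions:
# alpha -68, beta 178, gamma 54, delta 82, epsilon -153, zeta -71 deg.
attach_sugar_backbone <- function(base_xyz, code, c1p, chi, P, taum) {
  tpl <- get_template(code)
  Ng <- base_xyz[tpl$glyco, ]
  Cref <- base_xyz[tpl$chi_ref, ]
  glyco_bond <- vnorm(Ng - c1p)

  # O4' from chi about the glycosidic bond
  O4p <- nerf_place(Cref, Ng, c1p, 1.414, 108.2, chi)

  ring <- ribose_ring_cached(P, taum)
  # rigid-place the ring: C1' on anchor, O4' on the placed O4', and the
  # rotation about that axis chosen so angle(C2'-C1'-Ng) is 113.5 deg with
  # beta-D chirality.
  rl <- sweep(ring, 2, ring["C1'", ])
  axis_l <- unitv(rl["O4'", ])
  axis_g <- unitv(O4p - c1p)
  v <- cross3(axis_l, axis_g)
  R0 <- if (vnorm(v) < 1e-10) diag(3) else
    rot_about_axis(v, rad2deg(atan2(vnorm(v), sum(axis_l * axis_g))))
  place_t <- function(t) {
    R <- rot_about_axis(axis_g, t) %*% R0
    sweep(t(R %*% t(rl)), 2, c1p, "+")
  }
  score <- function(t) {
    m <- place_t(t)
    abs(angle3(m["C2'", ], c1p, Ng) - 113.5)
  }
  ts <- seq(0, 359, by = 1)
  sc <- vapply(ts, score, 0)
  # two near-solutions (mirror pair); resolve by chirality of C1'
  ord <- order(sc)
  picks <- ts[ord[1]]
  for (t in ts[ord]) {
    if (min(abs(angle_diff(t, picks))) > 30) { picks <- c(picks, t); break }
  }
  cand <- lapply(picks, function(t0)
    stats::optimize(score, c(t0 - 2, t0 + 2))$minimum)
  chir <- function(m) {
    # signed volume of (Ng, O4', C2') about C1'
    sign(sum(cross3(Ng - c1p, m["O4'", ] - c1p) * (m["C2'", ] - c1p)))
  }
  mats <- lapply(cand, place_t)
  sgn <- vapply(mats, chir, 0)
  sel <- which(sgn > 0)
  m <- if (length(sel)) mats[[sel[1]]] else mats[[1]]

  out <- list(`C1'` = c1p, `C2'` = m["C2'", ], `C3'` = m["C3'", ],
              `C4'` = m["C4'", ], `O4'` = m["O4'", ])

  # exocyclic sugar substituents
  d_h1 <- tetra_fill(c1p, rbind(Ng, m["C2'", ], m["O4'", ]))
  out$`H1'` <- c1p + 1.09 * d_h1[1, ]
  d2 <- tetra_fill(m["C2'", ], rbind(c1p, m["C3'", ]), n_new = 2)
  # O2' on the face away from the base
  o2_cand <- rbind(m["C2'", ] + 1.42 * d2[1, ], m["C2'", ] + 1.42 * d2[2, ])
  far <- which.max(c(vnorm(o2_cand[1, ] - Ng), vnorm(o2_cand[2, ] - Ng)))
  out$`O2'` <- o2_cand[far, ]
  out$`H2'` <- m["C2'", ] + 1.09 * d2[-far, ]

  nu4 <- dihedral(c1p, m["O4'", ], m["C4'", ], m["C3'", ])
  out$`C5'` <- nerf_place(c1p, m["O4'", ], m["C4'", ], 1.508, 109.5,
                          nu4 + 119)
  d_h4 <- tetra_fill(m["C4'", ], rbind(m["C3'", ], m["O4'", ], out$`C5'`))
  out$`H4'` <- m["C4'", ] + 1.09 * d_h4[1, ]
  out$`O5'` <- nerf_place(m["C3'", ], m["C4'", ], out$`C5'`, 1.423, 110.5, 54)
  out$P <- nerf_place(m["C4'", ], out$`C5'`, out$`O5'`, 1.595, 120.9, 178)
  o3_link <- nerf_place(out$`C5'`, out$`O5'`, out$P, 1.607, 104.0, -68)
  bis <- unitv(out$`O5'` - out$P) + unitv(o3_link - out$P)
  perp <- unitv(cross3(out$`O5'` - out$P, o3_link - out$P))
  half <- deg2rad(119.6 / 2)
  bdir <- -unitv(bis)
  op <- rbind(out$P + 1.485 * (cos(half) * bdir + sin(half) * perp),
              out$P + 1.485 * (cos(half) * bdir - sin(half) * perp))
  # OP2 is the anion oxygen on the major-groove face (nearer the base edge)
  near <- which.min(c(vnorm(op[1, ] - Ng), vnorm(op[2, ] - Ng)))
  out$OP2 <- op[near, ]
  out$OP1 <- op[-near, ]
  out$`O3'` <- nerf_place(out$`C5'`, m["C4'", ], m["C3'", ], 1.423, 110.0, 82)
  d_h3 <- tetra_fill(m["C3'", ], rbind(m["C2'", ], m["C4'", ], out$`O3'`))
  out$`H3'` <- m["C3'", ] + 1.09 * d_h3[1, ]

  do.call(rbind, out)
}

helix_transform <- function(params, level) {
  Ri <- rot_y(params$inclination)
  Rz_i <- rot_z((level - 1) * params$twist)
  shift <- c(params$x_disp, 0, 0)
  lift <- c(0, 0, (level - 1) * params$rise)
  function(m) {
    m2 <- t(Ri %*% t(m))
    m2 <- sweep(m2, 2, shift, "+")
    sweep(t(Rz_i %*% t(m2)), 2, lift, "+")
  }
}

flip_pair <- function(m) { m[, 2] <- -m[, 2]; m[, 3] <- -m[, 3]; m }

build_nucleotide <- function(code, flipped, chi, P, taum) {
  tpl <- get_template(code)
  base_xyz <- tpl$coords
  c1p <- tpl$c1p
  if (flipped) {
    base_xyz <- flip_pair(base_xyz)
    c1p <- c(c1p[1], -c1p[2], -c1p[3])
  }
  sb <- attach_sugar_backbone(base_xyz, code, c1p, chi, P, taum)
  rbind(sb, base_xyz)
}

element_of <- function(name) substr(gsub("[0-9']", "", name), 1, 1)

#' Build an idealized A-form duplex
#'
#' Constructs an all-atom model of the duplex described by \code{topo}:
#' strand-1 residues 1..N and strand-2 residues N+1..2N (each 5' to 3'),
#' with pseudouridine incorporated as a C-glycoside (C1'-C5 bond, imino
#' proton HN1, no H5) at the positions recorded in the topology.  The
#' construction is deterministic for fixed parameters.  Hydroxyl and C5'
#' hydrogens are omitted; all base hydrogens plus H1', H2', H3' and H4' are
#' present.
#'
#' @param topo a \code{duplex_topology}.
#' @param params an \code{aform_parameters} object.
#' @return a classified \code{conformation_frame}.
#' @examples
#' topo <- build_topology("UCAGPCAGU", "ACUGACUGA")
#' frame <- build_aform_duplex(topo)
#' @export
build_aform_duplex <- function(topo, params = aform_parameters()) {
  stopifnot(inherits(topo, "duplex_topology"))
  if (!inherits(params, "aform_parameters"))
    stop("params must come from aform_parameters()")
  N <- topo$N
  res_list <- vector("list", 2 * N)
  chi_of <- function(code) if (code == "PSU") params$chi_psu else params$chi_anti
  for (i in 1:N) {
    tr <- helix_transform(params, i)
    code1 <- topo$strand1[i]
    m1 <- build_nucleotide(code1, FALSE, chi_of(code1),
                           params$pucker_phase, params$pucker_amplitude)
    res_list[[i]] <- tr(m1)
    j <- 2 * N + 1 - i
    code2 <- topo$strand2[j - N]
    m2 <- build_nucleotide(code2, TRUE, chi_of(code2),
                           params$pucker_phase, params$pucker_amplitude)
    res_list[[j]] <- tr(m2)
  }
  rows <- list()
  for (r in 1:(2 * N)) {
    m <- res_list[[r]]
    # 5'-terminal residues (first of each strand) carry no phosphate
    if (r == 1 || r == N + 1)
      m <- m[!rownames(m) %in% c("P", "OP1", "OP2"), , drop = FALSE]
    rows[[r]] <- data.frame(
      name = rownames(m),
      element = vapply(rownames(m), element_of, ""),
      residue_index = r,
      residue_code = residue_code(topo, r),
      klass = NA_character_,
      x = m[, 1], y = m[, 2], z = m[, 3],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  frame <- conformation_frame(do.call(rbind, rows))
  frame <- refine_phosphates(frame, topo)
  classify_atoms(frame, topo)
}

# The per-nucleotide backbone is built from canonical internal coordinates,
# which cannot simultaneously satisfy the inter-residue O3'(i-1)-P(i) bond
# under an arbitrary screw.  This deterministic post-pass jointly re-places
# the O5'-P arm of each non-terminal residue so that the phosphate actually
# bridges C5'(i) and O3'(i-1) at bond geometry while keeping at least van
# der Waals separation from both residues, and rebuilds OP1/OP2 around the
# refined phosphorus.  The torsions alpha/gamma/zeta of the final model are
# therefore emergent closure values, seeded from the canonical A-form ones.
refine_phosphates <- function(frame, topo) {
  at <- frame$atoms
  xyz <- frame_coords(frame)
  N <- topo$N
  for (r in seq_len(2 * N)) {
    if (r %in% c(1, N + 1)) next
    rp <- r - 1L
    if (!any(at$residue_index == r & at$name == "P")) next
    iP <- atom_index(frame, r, "P")
    iO5 <- atom_index(frame, r, "O5'")
    c5 <- atom_xyz(frame, r, "C5'")
    c4 <- atom_xyz(frame, r, "C4'")
    o3p <- atom_xyz(frame, rp, "O3'")
    c3p <- atom_xyz(frame, rp, "C3'")
    ctx <- which(at$residue_index %in% c(r, rp) &
                 !(at$residue_index == r &
                   at$name %in% c("P", "OP1", "OP2", "O5'", "C5'")) &
                 !(at$residue_index == rp & at$name == "O3'"))
    ctx_xyz <- xyz[ctx, , drop = FALSE]
    clash <- function(p, dmin = 2.4) {
      d2 <- rowSums(sweep(ctx_xyz, 2, p)^2)
      sum(pmax(0, dmin - sqrt(d2))^2)
    }
    penal <- function(x) {
      o5 <- x[1:3]; p <- x[4:6]
      100 * ((vnorm(o5 - c5) - 1.423)^2 +
             (vnorm(p - o5) - 1.595)^2 +
             (vnorm(p - o3p) - 1.607)^2) +
        ((angle3(c4, c5, o5) - 110.5)^2 +
         (angle3(c5, o5, p) - 120.9)^2 +
         (angle3(c3p, o3p, p) - 119.7)^2 +
         (angle3(o5, p, o3p) - 104.0)^2) / 200 +
        10 * (clash(o5) + clash(p)) +
        anchor_w * (sum((o5 - o5_0)^2) + sum((p - p_0)^2))
    }
    o5_0 <- xyz[iO5, ]; p_0 <- xyz[iP, ]
    anchor_w <- 8   # keeps the arm in the canonical A-form rotamer basin
    o <- stats::optim(c(o5_0, p_0), penal, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12))
    o5_new <- o$par[1:3]
    p_new <- o$par[4:6]
    # rebuild the anionic oxygens around the refined phosphorus
    bis <- unitv(o5_new - p_new) + unitv(o3p - p_new)
    perp <- unitv(cross3(o5_new - p_new, o3p - p_new))
    half <- deg2rad(119.6 / 2)
    bdir <- -unitv(bis)
    op <- rbind(p_new + 1.485 * (cos(half) * bdir + sin(half) * perp),
                p_new + 1.485 * (cos(half) * bdir - sin(half) * perp))
    code <- residue_code(topo, r)
    gl <- if (code == "PSU") "C5" else if (code %in% c("A", "G")) "N9" else "N1"
    ng <- atom_xyz(frame, r, gl)
    near <- which.min(c(vnorm(op[1, ] - ng), vnorm(op[2, ] - ng)))
    frame$atoms[iO5, c("x", "y", "z")] <- o5_new
    frame$atoms[iP, c("x", "y", "z")] <- p_new
    frame$atoms[atom_index(frame, r, "OP2"), c("x", "y", "z")] <- op[near, ]
    frame$atoms[atom_index(frame, r, "OP1"), c("x", "y", "z")] <- op[-near, ]
  }
  frame
}
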