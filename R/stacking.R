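# Molecular-mechanics base-stacking energies and the four-base step
# decomposition.
#
# For a base-pair step the four base fragments are labelled
#   A, B: strand-1 bases, 5' to 3';  D, C: their partners (A-D, B-C pair).
# The step stacking energy is
#   dE_AC,BD = E_ADBC - (E_AD + E_BC)
# where E_ADBC is the interaction energy of the complete four-base system
# and E_AD, E_BC the hydrogen-bonded pair energies; under pairwise-additive
# MM it equals E_AB + E_CD + E_AC + E_BD (intra- plus interstrand stacking).
#
# Step labels are written XY/WZ, strand 1 read 5' to 3', with W paired to X
# and Z to Y; "P" denotes pseudouridine (printed as the Greek letter by the
# formatting helpers).

#' Base fragment of one residue
#'
#' Extracts the base-classified atoms (ring plus exocyclic substituents and
#' their hydrogens, severed at the glycosidic bond) of a residue.
#'
#' @param frame a classified \code{conformation_frame}.
#' @param residue residue index.
#' @return list with \code{code}, \code{names}, \code{xyz}.
#' @export
base_fragment <- function(frame, residue) {
  at <- frame$atoms
  idx <- which(at$residue_index == residue & at$klass == "base")
  if (!length(idx)) stop("residue ", residue, " has no base atoms")
  code <- at$residue_code[idx[1]]
  expected <- base_atom_names(code)
  missing <- setdiff(expected, at$name[idx])
  if (length(missing))
    stop("residue ", residue, " lacks base atom(s): ",
         paste(missing, collapse = ", "))
  list(code = code, names = at$name[idx],
       xyz = frame_coords(frame)[idx, , drop = FALSE])
}

#' Pairwise nonbonded interaction energy of two fragments
#'
#' Coulomb sum k q_i q_j / r_ij (dielectric 1, no cutoff) plus
#' Lennard-Jones 4 eps \[(sigma/r)^12 - (sigma/r)^6\] with Lorentz-Berthelot
#' combining (arithmetic sigma, geometric epsilon).
#'
#' @param frag_i,frag_j fragments from \code{\link{base_fragment}} (or lists
#'   with \code{code}, \code{names}, \code{xyz}).
#' @param params \code{\link{default_forcefield}} table.
#' @return named numeric vector \code{c(elec=, vdw=, total=)} in kcal/mol.
#' @export
pair_energy <- function(frag_i, frag_j, params = default_forcefield()) {
  pi_ <- ff_lookup(params, frag_i$code, frag_i$names)
  pj <- ff_lookup(params, frag_j$code, frag_j$names)
  dx <- outer(frag_i$xyz[, 1], frag_j$xyz[, 1], "-")
  dy <- outer(frag_i$xyz[, 2], frag_j$xyz[, 2], "-")
  dz <- outer(frag_i$xyz[, 3], frag_j$xyz[, 3], "-")
  r <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(r < 0.5))
    stop("interatomic distance below 0.5 A: fragments clash or overlap")
  k <- attr(params, "coulomb_constant")
  elec <- sum(k * outer(pi_$charge, pj$charge) / r)
  sig <- outer(pi_$sigma, pj$sigma, "+") / 2
  eps <- sqrt(outer(pi_$epsilon, pj$epsilon))
  sr6 <- (sig / r)^6
  vdw <- sum(4 * eps * (sr6^2 - sr6))
  c(elec = elec, vdw = vdw, total = elec + vdw)
}

# interaction energy of a set of fragments taken as one system: sum over
# all atom pairs belonging to different fragments, accumulated in one flat
# pass (numerically independent of the six-pair-sum route).
multi_fragment_energy <- function(frags, params) {
  codes <- unlist(lapply(seq_along(frags), function(k)
    rep(frags[[k]]$code, length(frags[[k]]$names))))
  names_ <- unlist(lapply(frags, `[[`, "names"))
  xyz <- do.call(rbind, lapply(frags, `[[`, "xyz"))
  grp <- rep(seq_along(frags), vapply(frags, function(f) length(f$names), 0L))
  p <- ff_lookup(params, codes, names_)
  k <- attr(params, "coulomb_constant")
  n <- nrow(xyz)
  elec <- 0; vdw <- 0
  for (i in seq_len(n - 1)) {
    j <- which(grp[(i + 1):n] != grp[i]) + i
    if (!length(j)) next
    d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    if (any(d < 0.5)) stop("interatomic distance below 0.5 A")
    elec <- elec + sum(k * p$charge[i] * p$charge[j] / d)
    sig <- (p$sigma[i] + p$sigma[j]) / 2
    eps <- sqrt(p$epsilon[i] * p$epsilon[j])
    sr6 <- (sig / d)^6
    vdw <- vdw + sum(4 * eps * (sr6^2 - sr6))
  }
  c(elec = elec, vdw = vdw, total = elec + vdw)
}

#' Residue indices of the four bases of step i
#'
#' @param topo a \code{duplex_topology}.
#' @param i step index (pairs i and i+1).
#' @return named integer vector (A, B, C, D).
#' @export
step_residues <- function(topo, i) {
  if (i < 1 || i >= topo$N) stop("step index out of range")
  c(A = i, B = i + 1L,
    C = topo$pairing[i + 1L], D = topo$pairing[i])
}

step_label_letter <- function(code) if (code == "PSU") "P" else code

#' Label of the step at position i
#' @inheritParams step_residues
#' @return character like \code{"CP/GA"} (strand-1 5'-CPsi with partners).
#' @export
step_label <- function(topo, i) {
  rs <- step_residues(topo, i)
  l <- vapply(rs, function(r) step_label_letter(residue_code(topo, r)), "")
  paste0(l["A"], l["B"], "/", l["D"], l["C"])
}

#' Four-base step stacking-energy decomposition
#'
#' Computes the tetramer interaction energy E_ADBC, the hydrogen-bonded
#' pair energies E_AD and E_BC, the intrastrand (E_AB, E_CD) and
#' interstrand (E_AC, E_BD) stacking terms, and the step stacking energy
#' dE_AC,BD = E_ADBC - E_AD - E_BC, each split into electrostatic and van
#' der Waals components.
#'
#' @param frame a classified \code{conformation_frame}.
#' @param topo the matching \code{duplex_topology}.
#' @param i step index (between pairs i and i+1).
#' @param params force-field table.
#' @return object of class \code{step_stacking}: list of energy components
#'   (each \code{c(elec, vdw, total)}), the \code{label}, and the
#'   \code{psu_charges} provenance flag.
#' @export
step_stacking_energy <- function(frame, topo, i,
                                 params = default_forcefield()) {
  rs <- step_residues(topo, i)
  fr <- lapply(rs, function(r) base_fragment(frame, r))
  e <- list(
    E_ADBC = multi_fragment_energy(fr[c("A", "D", "B", "C")], params),
    E_AD = pair_energy(fr$A, fr$D, params),
    E_BC = pair_energy(fr$B, fr$C, params),
    E_AB = pair_energy(fr$A, fr$B, params),
    E_CD = pair_energy(fr$C, fr$D, params),
    E_AC = pair_energy(fr$A, fr$C, params),
    E_BD = pair_energy(fr$B, fr$D, params))
  e$dE_step <- e$E_ADBC - e$E_AD - e$E_BC
  structure(c(e, list(label = step_label(topo, i), step = i,
                      psu_charges = attr(params, "psu_charges"))),
            class = "step_stacking")
}

#' @export
print.step_stacking <- function(x, ...) {
  cat(sprintf("step %s: dE = %.3f kcal/mol (elec %.3f, vdw %.3f)\n",
              format_step_label(x$label), x$dE_step["total"],
              x$dE_step["elec"], x$dE_step["vdw"]))
  invisible(x)
}

#' Pretty-print a step or motif label with the Greek letter
#' @param label ASCII label using "P" for pseudouridine.
#' @return display label.
#' @export
format_step_label <- function(label) gsub("P", "\u03a8", label)

#' Step stacking energy averaged over trajectory frames
#'
#' @param traj a \code{trajectory} of classified frames.
#' @param topo the \code{duplex_topology}.
#' @param i step index.
#' @param params force-field table.
#' @return list with \code{mean}, \code{sd} (of the total step energy over
#'   frames), \code{label}, \code{n_frames} and per-frame values.
#' @export
step_stacking_series <- function(traj, topo, i,
                                 params = default_forcefield()) {
  vals <- vapply(traj$frames, function(fr)
    step_stacking_energy(fr, topo, i, params)$dE_step[["total"]], 0)
  list(label = step_label(topo, i), mean = mean(vals),
       sd = stats::sd(vals), n_frames = length(vals), values = vals)
}

#' The eight unique base-pair steps containing a central Psi-A pair
#'
#' Four steps with the neighbouring pair 5' of Psi (XP) and four with it 3'
#' (PX); under the strand-exchange symmetry of a step these eight are all
#' distinct.  Deterministic order: 5'-Psi steps PA, PC, PG, PU, then AP,
#' CP, GP, UP.
#'
#' @return data.frame with \code{label} and base identities A, B, C, D.
#' @export
enumerate_unique_steps <- function() {
  nb <- c("A", "C", "G", "U")
  rows <- list()
  for (x in nb)
    rows[[length(rows) + 1]] <-
      data.frame(label = paste0("P", x, "/A", wc_letter(x)),
                 A = "PSU", B = x, C = wc_letter(x), D = "A")
  for (x in nb)
    rows[[length(rows) + 1]] <-
      data.frame(label = paste0(x, "P/", wc_letter(x), "A"),
                 A = x, B = "PSU", C = "A", D = wc_letter(x))
  do.call(rbind, rows)
}

wc_letter <- function(x) c(A = "U", U = "A", G = "C", C = "G", P = "A")[[x]]

#' The sixteen unique trinucleotide motifs with a central Psi-A pair
#' @return character vector of motif labels \code{XPZ} (strand-1 5' to 3').
#' @export
enumerate_trinucleotide_motifs <- function() {
  nb <- c("A", "C", "G", "U")
  as.vector(t(outer(nb, nb, function(x, z) paste0(x, "P", z))))
}

#' Stacking-energy change upon U -> Psi substitution for one step
#'
#' @param dec_mod \code{step_stacking} of the modified (Psi) step.
#' @param dec_unmod \code{step_stacking} of its unmodified counterpart
#'   (same step with U in place of Psi).
#' @return list with \code{label} (modified form), \code{ddE}
#'   (\code{c(elec, vdw, total)}, kcal/mol), and \code{stabilizing}
#'   (TRUE when total ddE < 0).
#' @export
modification_delta <- function(dec_mod, dec_unmod) {
  if (gsub("P", "U", dec_mod$label) != dec_unmod$label)
    stop("steps are not homologous: ", dec_mod$label, " vs ",
         dec_unmod$label)
  dd <- dec_mod$dE_step - dec_unmod$dE_step
  list(label = dec_mod$label, ddE = dd,
       stabilizing = unname(dd["total"] < 0),
       psu_charges = dec_mod$psu_charges)
}

#' Additive trinucleotide predictions from the dinucleotide table
#'
#' The stacking-energy change of a trinucleotide motif 5'-X Psi Z is
#' predicted as the sum of its two constituent steps: ddE(XPZ) = ddE(XP) +
#' ddE(PZ).  The result is sorted by increasing ddE (most stabilized
#' first).
#'
#' @param ddE_table data.frame with columns \code{label} (the eight step
#'   labels of \code{\link{enumerate_unique_steps}}) and \code{ddE}.
#' @return data.frame with \code{motif}, \code{ddE}, \code{rank}, plus
#'   attributes \code{most_stabilized} / \code{least_stabilized}.
#' @export
trinucleotide_prediction <- function(ddE_table) {
  steps <- enumerate_unique_steps()$label
  missing <- setdiff(steps, ddE_table$label)
  if (length(missing))
    stop("missing dinucleotide step(s): ", paste(missing, collapse = ", "))
  lk <- function(lab) {
    v <- ddE_table$ddE[match(lab, ddE_table$label)]
    if (anyNA(v)) stop("unknown step label")
    v
  }
  motifs <- enumerate_trinucleotide_motifs()
  x <- substr(motifs, 1, 1); z <- substr(motifs, 3, 3)
  first <- paste0(x, "P/", vapply(x, wc_letter, ""), "A")
  second <- paste0("P", z, "/A", vapply(z, wc_letter, ""))
  val <- lk(first) + lk(second)
  out <- data.frame(motif = motifs, ddE = val)[order(val), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "most_stabilized") <- out$motif[1]
  attr(out, "least_stabilized") <- out$motif[nrow(out)]
  out
}

#' Import externally computed (e.g. quantum-chemical) step energies
#'
#' Accepts a table of step stacking energies for the modified and
#' unmodified forms, validates the labels against
#' \code{\link{enumerate_unique_steps}}, and produces the ddE table on
#' which the trinucleotide machinery runs unchanged.
#'
#' @param table data.frame (or CSV path) with columns \code{label},
#'   \code{e_modif}, \code{e_unmodif} (kcal/mol).
#' @return data.frame with \code{label}, \code{ddE} and attribute
#'   \code{source = "QM imported"}.
#' @export
import_qm_energies <- function(table) {
  if (is.character(table)) table <- utils::read.csv(table)
  need <- c("label", "e_modif", "e_unmodif")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(table$label))
    stop("duplicate step label(s): ",
         paste(unique(table$label[duplicated(table$label)]), collapse = ", "))
  known <- enumerate_unique_steps()$label
  bad <- setdiff(table$label, known)
  if (length(bad)) stop("unknown step label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(label = table$label,
                    ddE = table$e_modif - table$e_unmodif)
  attr(out, "source") <- "QM imported"
  out
}

#' Spearman rank agreement between two ddE tables
#' @param a,b data.frames with \code{label} and \code{ddE}.
#' @return Spearman correlation of the ddE values over shared labels.
#' @export
ddE_rank_correlation <- function(a, b) {
  shared <- intersect(a$label, b$label)
  stats::cor(a$ddE[match(shared, a$label)], b$ddE[match(shared, b$label)],
             method = "spearman")
}

#' Capped base monomer for tetramer preparation
#'
#' The standard-frame base template with the glycosidic position capped by
#' a hydrogen along the bond to C1' (N-H 1.01 A for the N-glycosides, C-H
#' 1.09 A for pseudouridine), the convention used for the exported
#' quantum-chemistry monomers.
#'
#' @param code residue code.
#' @return coordinate matrix with rownames; the cap atom is \code{"HCAP"}.
#' @export
base_monomer <- function(code) {
  tpl <- get_template(code)
  m <- tpl$coords
  gl <- m[tpl$glyco, ]
  bond <- if (tpl$glyco == "C5") 1.09 else 1.01
  cap <- gl + bond * unitv(tpl$c1p - gl)
  rbind(m, HCAP = cap)
}

#' Prepare an idealized tetramer on the scaffold of a structure
#'
#' Superposes the capped idealized monomer of each of the four bases of a
#' step onto the corresponding base of the scaffold structure (least
#' squares over the ring atoms) and returns the transformed monomers, ready
#' for \code{\link{export_qm_geometry}}.
#'
#' @param frame scaffold structure (e.g. the representative of the most
#'   populated cluster).
#' @param topo the \code{duplex_topology}.
#' @param i step index.
#' @return list with \code{fragments} (named list A, B, C, D of coordinate
#'   matrices), \code{fit_rmsd} (per base, Angstrom) and \code{flags}
#'   (bases with fit RMSD above 0.5 A).
#' @export
prepare_tetramer_geometry <- function(frame, topo, i) {
  rs <- step_residues(topo, i)
  frags <- list(); rms <- numeric(0)
  for (nm in c("A", "B", "C", "D")) {
    r <- rs[[nm]]
    code <- residue_code(topo, r)
    tpl <- get_template(code)
    mono <- base_monomer(code)
    ring <- tpl$ring
    obs <- t(vapply(ring, function(a) atom_xyz(frame, r, a), numeric(3)))
    sp <- superpose(tpl$coords[ring, , drop = FALSE], obs)
    frags[[nm]] <- apply_superposition(sp, mono)
    rownames(frags[[nm]]) <- rownames(mono)
    rms[nm] <- sp$rmsd
  }
  flags <- names(rms)[rms > 0.5]
  if (length(flags))
    warning("distorted base(s) in step ", step_label(topo, i), ": ",
            paste(flags, collapse = ", "))
  list(fragments = frags, fit_rmsd = rms, flags = flags)
}
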