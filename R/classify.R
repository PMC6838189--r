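# Atom classification: every solute atom is base, sugar or backbone; waters
# and ions keep their own classes.  The backbone set is the phosphodiester
# chain P, OP1, OP2, O5', C5', C4', C3', O3' with their attached hydrogens;
# the sugar set is the remaining ribose atoms (C1', C2', O4', O2' and
# hydrogens); everything else of a nucleotide is base.

BACKBONE_HEAVY <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")
BACKBONE_H <- c("H5'", "H5''", "H4'", "H3'", "HO5'", "HO3'")
SUGAR_HEAVY <- c("C1'", "C2'", "O4'", "O2'")
SUGAR_H <- c("H1'", "H2'", "HO2'")

#' Base-atom names of a residue code
#'
#' The atoms classified as \code{base}: ring atoms, exocyclic substituents
#' and their hydrogens, severed at the glycosidic bond.  Pseudouridine has
#' the imino proton HN1 and no H5.
#'
#' @param code residue code (\code{A}, \code{U}, \code{G}, \code{C},
#'   \code{PSU}).
#' @return character vector of atom names.
#' @export
base_atom_names <- function(code) {
  switch(code,
    A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4",
          "H8", "H2", "H61", "H62"),
    G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4",
          "H8", "H1", "H21", "H22"),
    C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6",
          "H41", "H42", "H5", "H6"),
    U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6",
          "H3", "H5", "H6"),
    # pseudouridine: uracil ring attached through C5; N1 carries the extra
    # imino proton HN1 and there is no H5
    PSU = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6",
            "H3", "H6", "HN1"),
    stop("unknown residue code: ", code))
}

#' Classify the atoms of a frame against a duplex topology
#'
#' Assigns the \code{klass} column (base / sugar / backbone) for every solute
#' atom.  Water (\code{HOH}) and ion records are classified as \code{water}
#' and \code{ion}.  Classification is total: an atom name that belongs to no
#' class for its residue is an error.
#'
#' @param frame a \code{conformation_frame}.
#' @param topo the \code{duplex_topology} the frame represents.
#' @return the frame with \code{klass} filled in.
#' @export
classify_atoms <- function(frame, topo) {
  at <- frame$atoms
  klass <- rep(NA_character_, nrow(at))
  is_w <- at$residue_code %in% c("HOH", "WAT")
  is_ion <- at$residue_code %in% c("NA", "K", "CL", "MG", "NA+", "K+", "CL-")
  klass[is_w] <- "water"
  klass[is_ion] <- "ion"
  solute <- !(is_w | is_ion)
  if (any(at$residue_index[solute] < 1 | at$residue_index[solute] > 2 * topo$N))
    stop("solute residue index outside 1..", 2 * topo$N)
  for (i in which(solute)) {
    code <- residue_code(topo, at$residue_index[i])
    nm <- at$name[i]
    klass[i] <-
      if (nm %in% BACKBONE_HEAVY || nm %in% BACKBONE_H) "backbone"
      else if (nm %in% SUGAR_HEAVY || nm %in% SUGAR_H) "sugar"
      else if (nm %in% base_atom_names(code)) "base"
      else stop("unclassifiable atom '", nm, "' in residue ",
                at$residue_index[i], " (", code, ")")
  }
  frame$atoms$klass <- klass
  frame
}

#' Atom-name normalization used by all readers
#'
#' Maps legacy phosphate oxygen names O1P/O2P to OP1/OP2 and asterisk sugar
#' names (\code{C1*}) to primed names (\code{C1'}); the pseudouridine imino
#' proton may be spelled H1 or HN1 in deposited files and is normalized to
#' HN1 for PSU residues.
#'
#' @param name character vector of atom names.
#' @param residue_code character vector of residue codes (same length).
#' @return normalized names.
#' @export
normalize_atom_names <- function(name, residue_code) {
  name <- gsub("*", "'", name, fixed = TRUE)
  name[name == "O1P"] <- "OP1"
  name[name == "O2P"] <- "OP2"
  psu <- residue_code == "PSU" & name == "H1"
  name[psu] <- "HN1"
  name
}
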