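# Nonbonded force-field parameters for nucleobase atoms.

#' Coulomb constant in kcal A mol^-1 e^-2
#' @export
COULOMB_CONSTANT <- 332.0637

#' Load the bundled nonbonded base-atom parameter table
#'
#' Per-atom partial charges (elementary charge units) and Lennard-Jones
#' parameters (sigma in Angstrom, epsilon in kcal/mol) for the base atoms of
#' A, U, G, C and pseudouridine (PSU).  The A/U/G/C charges are the classic
#' AMBER (Cornell-type) nucleobase charges, which are unchanged for base atoms
#' across the ff99-family refinements; the LJ values come from the matching
#' parm99 atom-type classes.  Only nonbonded terms are stored: the package
#' never evaluates bonds, angles or dihedrals.
#'
#' The published pseudouridine charge set is not redistributable here, so the
#' PSU entries are a clearly flagged surrogate derived from uridine: the
#' glycosidic role moves from N1 to C5 (C5 takes U's N1 charge), N1 and HN1
#' take U's imino N3/H3 values, H5 is absent, and HN1 is shifted so that the
#' PSU base-fragment net charge equals uridine's.  Every report produced from
#' these parameters carries the flag \code{psu_charges = "surrogate"}.
#'
#' @param path optional path to an alternative CSV with the same columns
#'   (\code{residue_code}, \code{atom_name}, \code{charge}, \code{sigma},
#'   \code{epsilon}); lines beginning with \code{#} are ignored.  Use this to
#'   override the surrogate with an actual published PSU set.
#' @return object of class \code{forcefield_parameters}: a data.frame of the
#'   four columns above with attributes \code{coulomb_constant},
#'   \code{combining_rule} (\code{"lorentz-berthelot"}) and
#'   \code{psu_charges} (\code{"surrogate"} for the bundled table,
#'   \code{"user"} for an override).
#' @export
default_forcefield <- function(path = NULL) {
  user <- !is.null(path)
  if (!user)
    path <- system.file("extdata", "forcefield_base_atoms.csv",
                        package = "psihelix", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue_code", "atom_name", "charge", "sigma", "epsilon")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$sigma < 0) || any(tab$epsilon < 0))
    stop("sigma and epsilon must be non-negative")
  if (anyDuplicated(tab[, c("residue_code", "atom_name")]))
    stop("duplicate (residue_code, atom_name) entry in parameter table")
  structure(tab[, need],
            coulomb_constant = COULOMB_CONSTANT,
            combining_rule = "lorentz-berthelot",
            psu_charges = if (user) "user" else "surrogate",
            class = c("forcefield_parameters", "data.frame"))
}

# Look up (charge, sigma, epsilon) for a set of atoms; errors list every
# missing atom so the caller can see what is unparameterized.
ff_lookup <- function(params, residue_code, atom_name) {
  key <- paste(residue_code, atom_name)
  tab_key <- paste(params$residue_code, params$atom_name)
  idx <- match(key, tab_key)
  if (anyNA(idx))
    stop("unparameterized atom(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  params[idx, c("charge", "sigma", "epsilon")]
}
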