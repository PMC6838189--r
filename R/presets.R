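# The duplex set under study: 9-mer RNA duplexes with a central Psi-A (or
# U-A) pair, differing only in the base pairs flanking the central pair.
# Strand-1 position 5 carries the modification ("P" = pseudouridine).

#' Sequences of the studied duplexes
#'
#' Named presets for the four pseudouridine-modified 9-mer duplexes
#' (central motifs GPC, CPG, APU, UPA read along strand 1) and their
#' unmodified counterparts (GUC, CUG, AUU, UUA).  Both strands are given
#' 5' to 3'.
#'
#' @return named list; each element has \code{strand1}, \code{strand2} and
#'   \code{mods}.
#' @export
duplex_presets <- function() {
  list(
    GPC = list(strand1 = "UCAGPCAGU", strand2 = "ACUGACUGA", mods = 5),
    GUC = list(strand1 = "UCAGUCAGU", strand2 = "ACUGACUGA", mods = integer()),
    CPG = list(strand1 = "UCACPGAGU", strand2 = "ACUCAGUGA", mods = 5),
    CUG = list(strand1 = "UCACUGAGU", strand2 = "ACUCAGUGA", mods = integer()),
    APU = list(strand1 = "UCAAPUAGU", strand2 = "ACUAAUUGA", mods = 5),
    AUU = list(strand1 = "UCAAUUAGU", strand2 = "ACUAAUUGA", mods = integer()),
    UPA = list(strand1 = "UCAUPAAGU", strand2 = "ACUUAAUGA", mods = 5),
    UUA = list(strand1 = "UCAUUAAGU", strand2 = "ACUUAAUGA", mods = integer()))
}

#' Topology of a named duplex preset
#'
#' @param name preset name, e.g. \code{"CPG"} (modified) or \code{"CUG"}
#'   (its unmodified counterpart).
#' @return a \code{duplex_topology}.
#' @export
duplex_preset <- function(name) {
  p <- duplex_presets()[[name]]
  if (is.null(p)) stop("unknown duplex preset: ", name)
  build_topology(p$strand1, p$strand2, p$mods)
}

#' Unmodified counterpart of a modified preset name
#' @param name modified preset name (\code{"GPC"}, \code{"CPG"},
#'   \code{"APU"}, \code{"UPA"}).
#' @return the reference preset name.
#' @export
reference_preset <- function(name) {
  map <- c(GPC = "GUC", CPG = "CUG", APU = "AUU", UPA = "UUA")
  out <- map[name]
  if (anyNA(out)) stop("no unmodified counterpart for: ",
                       paste(name[is.na(out)], collapse = ", "))
  unname(out)
}
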