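# Duplex topology: sequences, Watson-Crick pairing, modification sites.

RESIDUE_CODES <- c("A", "U", "G", "C", "PSU")

#' Watson-Crick complement of a residue code
#'
#' Pseudouridine (\code{"PSU"}) pairs exactly as uridine: its Watson-Crick
#' face is unchanged by the C-glycosidic rearrangement.
#'
#' @param code character vector of residue codes.
#' @return character vector of complementary codes.
#' @export
wc_complement <- function(code) {
  map <- c(A = "U", U = "A", G = "C", C = "G", PSU = "A")
  bad <- setdiff(code, names(map))
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  unname(map[code])
}

parse_strand <- function(x) {
  if (length(x) == 1 && is.character(x) && !x[1] %in% RESIDUE_CODES) {
    # accept a compact string, with "P" standing for pseudouridine
    ch <- strsplit(x, "")[[1]]
    ch[ch %in% c("P", "p")] <- "PSU"
    x <- ch
  }
  x <- toupper(x)
  bad <- setdiff(x, RESIDUE_CODES)
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  x
}

#' Build a duplex topology
#'
#' Residues are numbered 1..N along strand 1 (5' to 3') and N+1..2N along
#' strand 2 (5' to 3'), so that strand-1 residue i pairs with residue
#' 2N + 1 - i.  For the 9-mer duplexes analysed here the modified residue 5
#' pairs with residue 14.
#'
#' @param strand1,strand2 residue codes 5' to 3', either as character vectors
#'   of codes in \code{A, U, G, C, PSU} or as compact strings in which
#'   \code{"P"} denotes pseudouridine (e.g. \code{"UCACPGAGU"}).
#' @param mods integer vector of strand-1 positions carrying pseudouridine.
#'   Positions already spelled \code{PSU} in \code{strand1} are kept as well.
#' @return an object of class \code{duplex_topology} with elements
#'   \code{strand1}, \code{strand2}, \code{N}, \code{pairing} (integer vector
#'   over residues 1..2N), and \code{mod_positions}.
#' @examples
#' topo <- build_topology("UCACPGAGU", "ACUCAGUGA")
#' topo$pairing[5]   # 14: the PSU5-A14 pair
#' @export
build_topology <- function(strand1, strand2, mods = integer()) {
  s1 <- parse_strand(strand1)
  s2 <- parse_strand(strand2)
  if (length(s1) != length(s2))
    stop("strands differ in length (", length(s1), " vs ", length(s2), ")")
  N <- length(s1)
  mods <- sort(unique(c(as.integer(mods), which(s1 == "PSU"))))
  if (any(mods < 1 | mods > N)) stop("modification position out of range")
  for (m in mods) {
    if (!s1[m] %in% c("U", "PSU"))
      stop("modification at position ", m,
           " is not at a uridine site (found ", s1[m], ")")
    s1[m] <- "PSU"
  }
  partner <- s2[N:1]   # residue opposite strand-1 residue i
  ok <- wc_complement(s1) == partner
  if (!all(ok))
    stop("non-complementary base pair at strand-1 position(s): ",
         paste(which(!ok), collapse = ", "))
  pairing <- c((2 * N):(N + 1), N:1)
  structure(
    list(strand1 = s1, strand2 = s2, N = N,
         pairing = as.integer(pairing), mod_positions = mods),
    class = "duplex_topology")
}

#' @export
print.duplex_topology <- function(x, ...) {
  fmt <- function(s) paste(ifelse(s == "PSU", "\u03a8", s), collapse = "")
  cat("RNA duplex topology, ", x$N, " base pairs\n", sep = "")
  cat("  5'-", fmt(x$strand1), "-3'\n", sep = "")
  cat("  3'-", fmt(rev(x$strand2)), "-5'\n", sep = "")
  if (length(x$mod_positions))
    cat("  pseudouridine at strand-1 position(s): ",
        paste(x$mod_positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Residue code at a (1..2N) residue index
#' @param topo a \code{duplex_topology}.
#' @param i residue index over the duplex.
#' @return residue code.
#' @export
residue_code <- function(topo, i) {
  stopifnot(inherits(topo, "duplex_topology"))
  ifelse(i <= topo$N, topo$strand1[i], topo$strand2[i - topo$N])
}
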