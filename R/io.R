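# Readers and writers: multi-model PDB (canonical), plain XYZ frame lists
# (synthetic-data dialect), and XYZ export of stacked tetramers for external
# quantum-chemistry software.

RESNAME_MAP <- c(A = "A", U = "U", G = "G", C = "C", PSU = "PSU",
                 RA = "A", RU = "U", RG = "G", RC = "C",
                 ADE = "A", URA = "U", GUA = "G", CYT = "C",
                 HOH = "HOH", WAT = "HOH",
                 "NA" = "NA", K = "K", CL = "CL", MG = "MG")

#' Read a multi-model PDB file as a trajectory/ensemble
#'
#' Parses ATOM/HETATM records of a (possibly multi-model) PDB stream.
#' Waters (HOH/WAT) and monatomic ions are recognized; alternate locations
#' are resolved to the highest occupancy; legacy atom names (O1P/O2P,
#' asterisks) are normalized; pseudouridine is recognized by residue name
#' PSU.  Residues are renumbered 1..n in order of first appearance; water
#' and ion residues continue the numbering after the solute.
#'
#' @param path file path (or connection) of the PDB file.
#' @param dt time spacing to assign between models, ps.
#' @return a \code{trajectory} whose frames are the models, with attribute
#'   \code{source} naming the file.  All models must share one atom roster;
#'   a mismatch is an error naming the offending model.
#' @export
read_multimodel_pdb <- function(path, dt = 10) {
  lines <- readLines(path)
  model_breaks <- grepl("^MODEL", lines)
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(atom_lines)) stop("no ATOM/HETATM records found")
  model_id <- cumsum(model_breaks)
  if (!any(model_breaks)) model_id[] <- 1
  models <- split(which(atom_lines), model_id[atom_lines])
  models <- models[vapply(models, length, 0L) > 0]
  frames <- vector("list", length(models))
  for (k in seq_along(models)) {
    ln <- lines[models[[k]]]
    name <- trimws(substr(ln, 13, 16))
    altloc <- substr(ln, 17, 17)
    resname <- trimws(substr(ln, 18, 20))
    chain <- substr(ln, 22, 22)
    resseq <- trimws(substr(ln, 23, 26))
    x <- as.numeric(substr(ln, 31, 38))
    y <- as.numeric(substr(ln, 39, 46))
    z <- as.numeric(substr(ln, 47, 54))
    occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
    occ[is.na(occ)] <- 1
    elem <- trimws(substr(ln, 77, 78))
    code <- RESNAME_MAP[resname]
    if (anyNA(code))
      stop("unknown residue name(s): ",
           paste(unique(resname[is.na(code)]), collapse = ", "))
    name <- normalize_atom_names(name, code)
    # resolve altlocs: keep highest occupancy per (chain, resseq, name)
    key <- paste(chain, resseq, name)
    keep <- rep(TRUE, length(ln))
    if (any(altloc != " ")) {
      for (kk in unique(key[altloc != " "])) {
        idx <- which(key == kk)
        if (length(idx) > 1) keep[idx[-which.max(occ[idx])]] <- FALSE
      }
    }
    sol <- !(code %in% c("HOH", "NA", "K", "CL", "MG"))
    rkey <- paste(chain, resseq)
    ridx <- integer(length(ln))
    ridx[sol] <- match(rkey[sol], unique(rkey[sol]))
    # waters/ions keep their own residue groups, numbered after the solute
    if (any(!sol))
      ridx[!sol] <- max(ridx[sol], 0L) +
        match(rkey[!sol], unique(rkey[!sol]))
    if (any(is.na(elem) | elem == ""))
      elem <- vapply(name, element_of, "")
    at <- data.frame(name = name, element = elem,
                     residue_index = ridx, residue_code = unname(code),
                     klass = NA_character_, x = x, y = y, z = z,
                     stringsAsFactors = FALSE)[keep, ]
    at$klass[at$residue_code == "HOH"] <- "water"
    at$klass[at$residue_code %in% c("NA", "K", "CL", "MG")] <- "ion"
    frames[[k]] <- conformation_frame(at, time = (k - 1) * dt)
  }
  ref <- frames[[1]]$atoms
  for (k in seq_along(frames)) {
    a <- frames[[k]]$atoms
    if (nrow(a) != nrow(ref) ||
        !all(a$name == ref$name & a$residue_index == ref$residue_index))
      stop("model ", k, " does not match the atom roster of model 1")
  }
  tr <- trajectory(frames, dt = dt)
  attr(tr, "source") <- if (is.character(path)) basename(path) else "stream"
  tr
}

pdb_resname <- function(code) {
  ifelse(code == "PSU", "PSU", ifelse(code == "HOH", "HOH", code))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Fixed-column PDB output (3 decimals); round-trips through
#' \code{read_multimodel_pdb} bit-exactly at that precision.  Waters are
#' written as HETATM HOH with sequential residue numbers after the solute.
#'
#' @param traj a \code{trajectory} (a single \code{conformation_frame} is
#'   also accepted).
#' @param path output file path.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (inherits(traj, "conformation_frame")) traj <- trajectory(list(traj))
  if (!length(traj$frames)) stop("empty trajectory")
  if (nrow(traj$frames[[1]]$atoms) > 99999) stop("more than 99999 atoms")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(traj$frames) > 1
  for (k in seq_along(traj$frames)) {
    at <- traj$frames[[k]]$atoms
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    serial <- seq_len(nrow(at))
    is_w <- !is.na(at$klass) & at$klass %in% c("water", "ion")
    # water/ion "residue" numbering continues after the solute
    res_out <- at$residue_index
    if (any(is_w)) {
      nmax <- max(res_out[!is_w], 0)
      grp <- cumsum(is_w & at$name %in% c("O", "NA", "K", "CL", "MG"))
      res_out[is_w] <- nmax + grp[is_w]
    }
    rec <- ifelse(is_w, "HETATM", "ATOM  ")
    nm <- at$name
    nm_fmt <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), nm)
    lines <- sprintf("%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, serial, nm_fmt,
                     pdb_resname(at$residue_code), "A", res_out,
                     at$x, at$y, at$z, 1, 0, at$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(NULL)
}

#' Read a plain XYZ frame-list trajectory
#'
#' Dialect: repeated blocks of (atom count line, comment line "t = <ps>",
#' atom lines "label x y z").  Labels are "residueindex:residuecode:atomname"
#' as written by \code{write_xyz_frames}, or a bare element symbol.
#'
#' @param path input file.
#' @param dt frame spacing used when the comments carry no times, ps.
#' @return a \code{trajectory}.
#' @export
read_xyz_frames <- function(path, dt = 10) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop("expected an atom count at line ", i)
    cm <- lines[i + 1]
    tm <- suppressWarnings(as.numeric(sub(".*t *= *([-0-9.eE+]+).*", "\\1", cm)))
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    lab <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    labp <- strsplit(lab, ":", fixed = TRUE)
    full <- lengths(labp) == 3
    at <- data.frame(
      name = ifelse(full, vapply(labp, function(p) p[3], ""), lab),
      element = ifelse(full,
                       vapply(labp, function(p) element_of(p[3]), ""), lab),
      residue_index = ifelse(full,
                             as.integer(vapply(labp, `[`, "", 1)), 0L),
      residue_code = ifelse(full, vapply(labp, `[`, "", 2), "X"),
      klass = NA_character_,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
    at$klass[at$residue_code == "HOH"] <- "water"
    frames[[length(frames) + 1]] <-
      conformation_frame(at, time = if (is.na(tm)) (length(frames)) * dt else tm)
    i <- i + 2 + n
  }
  trajectory(frames, dt = dt)
}

#' Write a trajectory in the plain XYZ frame-list dialect
#' @param traj a \code{trajectory}.
#' @param path output file.
#' @export
write_xyz_frames <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    at <- fr$atoms
    writeLines(as.character(nrow(at)), con)
    writeLines(sprintf("t = %g", fr$time), con)
    writeLines(sprintf("%s:%s:%s %12.6f %12.6f %12.6f",
                       at$residue_index, at$residue_code, at$name,
                       at$x, at$y, at$z), con)
  }
  invisible(NULL)
}

#' Export a four-base stacked geometry for external QM software
#'
#' Writes an XYZ-format block of the four base fragments of a base-pair
#' step, each atom tagged with its fragment label (A, B, C or D) in the
#' comment column, suitable for setting up counterpoise-corrected
#' interaction-energy calculations externally.  Fragment labels: A and B are
#' the strand-1 bases (5' to 3'), D and C their partners, so A-D and B-C are
#' the hydrogen-bonded pairs.
#'
#' @param fragments named list of four coordinate matrices (rownames = atom
#'   names, hydrogens included) in order A, B, C, D.
#' @param path output file.
#' @param title comment-line text.
#' @export
export_qm_geometry <- function(fragments, path, title = "base-pair step tetramer") {
  if (length(fragments) != 4) stop("need exactly four fragments")
  labels <- c("A", "B", "C", "D")
  for (k in 1:4) {
    m <- fragments[[k]]
    if (is.null(m) || nrow(m) == 0) stop("fragment ", labels[k], " is empty")
    if (!any(grepl("^H", rownames(m))))
      stop("fragment ", labels[k], " has no hydrogens; capped monomers required")
  }
  n <- sum(vapply(fragments, nrow, 0L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(n), title), con)
  for (k in 1:4) {
    m <- fragments[[k]]
    el <- vapply(rownames(m), element_of, "")
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f  # %s %s",
                       el, m[, 1], m[, 2], m[, 3], labels[k], rownames(m)), con)
  }
  invisible(NULL)
}
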