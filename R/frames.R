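# Conformation frames and trajectories.
#
# A frame stores its atoms as a data.frame with columns
#   name, element, residue_index, residue_code, klass, x, y, z
# where klass is one of base / sugar / backbone / water / ion.  Water and
# ion residues carry residue code "HOH" / the ion name and residue indices
# that continue after the solute.

#' Construct a conformation frame
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{residue_index}, \code{residue_code}, \code{klass}, \code{x},
#'   \code{y}, \code{z}.  \code{klass} may be \code{NA} before
#'   \code{\link{classify_atoms}} has run.
#' @param box optional orthorhombic box lengths (numeric 3-vector, Angstrom).
#' @param time frame time in ps.
#' @return object of class \code{conformation_frame}.
#' @export
conformation_frame <- function(atoms, box = NULL, time = 0) {
  need <- c("name", "element", "residue_index", "residue_code",
            "klass", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in frame")
  if (!is.null(box)) stopifnot(length(box) == 3, all(box > 0))
  structure(list(atoms = atoms[, need], box = box, time = time),
            class = "conformation_frame")
}

#' @export
print.conformation_frame <- function(x, ...) {
  n_solute <- sum(!x$atoms$klass %in% c("water", "ion"), na.rm = TRUE)
  n_w <- sum(x$atoms$klass == "water", na.rm = TRUE)
  cat("conformation frame: ", nrow(x$atoms), " atoms (",
      n_solute, " solute, ", n_w, " water), t = ", x$time, " ps\n", sep = "")
  invisible(x)
}

#' Coordinates of a frame as an n x 3 matrix
#' @param frame a \code{conformation_frame}.
#' @param sel optional logical or integer atom selection.
#' @return numeric matrix with one row per selected atom.
#' @export
frame_coords <- function(frame, sel = NULL) {
  m <- as.matrix(frame$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

set_frame_coords <- function(frame, m, sel = NULL) {
  if (is.null(sel)) {
    frame$atoms[, c("x", "y", "z")] <- m
  } else {
    frame$atoms[sel, c("x", "y", "z")] <- m
  }
  frame
}

#' Index of a single named atom
#'
#' @param frame a \code{conformation_frame}.
#' @param residue_index residue number (1..2N for the duplex).
#' @param name PDB atom name, e.g. \code{"OP2"}.
#' @return integer row index into \code{frame$atoms}.
#' @export
atom_index <- function(frame, residue_index, name) {
  i <- which(frame$atoms$residue_index == residue_index &
             frame$atoms$name == name)
  if (length(i) != 1)
    stop("atom ", name, " of residue ", residue_index,
         if (length(i)) " is ambiguous" else " not found")
  i
}

#' Coordinates of a single named atom
#' @inheritParams atom_index
#' @return numeric 3-vector.
#' @export
atom_xyz <- function(frame, residue_index, name) {
  frame_coords(frame)[atom_index(frame, residue_index, name), ]
}

#' Construct a trajectory from a list of frames
#'
#' @param frames list of \code{conformation_frame} objects sharing one atom
#'   roster (same names, residues and order).
#' @param dt time between saved frames in ps (default 10, the write
#'   frequency used for the reference simulations).
#' @return object of class \code{trajectory}.
#' @export
trajectory <- function(frames, dt = 10) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  if (dt <= 0) stop("dt must be positive")
  ref <- frames[[1]]$atoms
  for (k in seq_along(frames)) {
    a <- frames[[k]]$atoms
    if (nrow(a) != nrow(ref) ||
        !all(a$name == ref$name & a$residue_index == ref$residue_index))
      stop("frame ", k, " does not match the atom roster of frame 1")
  }
  structure(list(frames = frames, dt = dt), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", length(x$frames), " frames, dt = ", x$dt, " ps, ",
      nrow(x$frames[[1]]$atoms), " atoms\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' All coordinates of a trajectory as an array
#' @param traj a \code{trajectory}.
#' @param sel optional atom selection applied to every frame.
#' @return numeric array n_sel x 3 x n_frames.
#' @export
traj_coords <- function(traj, sel = NULL) {
  mats <- lapply(traj$frames, frame_coords, sel = sel)
  array(unlist(mats), dim = c(nrow(mats[[1]]), 3, length(mats)))
}
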