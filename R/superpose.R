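# Least-squares rigid-body superposition (Kabsch) and the RMSD/RMSF
# machinery built on it.

#' Optimal rigid superposition of two coordinate sets
#'
#' Kabsch algorithm via singular value decomposition: finds the proper
#' rotation \code{R} and translation \code{t} minimizing
#' \code{sum |R x_i + t - y_i|^2} over the selected atoms of
#' \code{mobile} (x) and \code{reference} (y).
#'
#' @param mobile,reference n x 3 coordinate matrices (or objects accepted by
#'   \code{\link{frame_coords}}).
#' @param sel optional selection (logical or integer) applied to both.
#' @return object of class \code{superposition}: list with \code{rotation}
#'   (3 x 3, determinant +1), \code{translation} (length 3) and \code{rmsd}
#'   (Angstrom).  Apply with \code{apply_superposition}.
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  X <- as_coords(mobile, sel)
  Y <- as_coords(reference, sel)
  if (!all(dim(X) == dim(Y))) stop("selections differ in size")
  n <- nrow(X)
  if (n < 3) stop("need at least 3 atoms to superpose")
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  sx <- svd(Xc)$d
  if (sx[2] < 1e-8 * max(sx[1], 1))
    stop("degenerate (collinear) selection")
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- yc - as.vector(R %*% xc)
  fitted <- sweep(Xc %*% t(R), 2, yc, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("superposition: rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

as_coords <- function(x, sel = NULL) {
  if (inherits(x, "conformation_frame")) return(frame_coords(x, sel))
  m <- as.matrix(x)
  if (ncol(m) != 3) stop("coordinates must be n x 3")
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Apply a fitted superposition to coordinates
#' @param sp a \code{superposition}.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as_coords(coords) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Each frame is optimally superposed onto the reference over the selection
#' before the deviation is computed.
#'
#' @param traj a \code{trajectory}.
#' @param reference a \code{conformation_frame} or n x 3 matrix with the
#'   same roster.
#' @param sel atom selection (logical/integer over the roster); default all
#'   heavy solute atoms.
#' @return numeric vector of RMSDs (Angstrom), one per frame.
#' @export
rmsd_series <- function(traj, reference, sel = NULL) {
  if (is.null(sel)) sel <- heavy_solute_selection(traj$frames[[1]])
  if (!length(which_sel(sel, nrow(traj$frames[[1]]$atoms))))
    stop("empty selection")
  ref <- as_coords(reference, sel)
  vapply(traj$frames, function(fr)
    superpose(frame_coords(fr, sel), ref)$rmsd, 0)
}

which_sel <- function(sel, n) {
  if (is.logical(sel)) which(sel) else as.integer(sel)
}

heavy_solute_selection <- function(frame) {
  with(frame$atoms, element != "H" & !(klass %in% c("water", "ion")))
}

#' Iterated mean structure of a set of frames
#'
#' Superposes all frames to the first, averages, then superposes all frames
#' onto the average and re-averages (one iteration), which removes the
#' dependence on the arbitrary initial reference.
#'
#' @param traj a \code{trajectory}.
#' @param sel selection used for fitting (default heavy solute atoms).
#' @return list with \code{mean} (n x 3 matrix over the full roster) and
#'   \code{fitted} (array n x 3 x n_frames of the superposed frames).
#' @export
mean_structure <- function(traj, sel = NULL) {
  if (is.null(sel)) sel <- heavy_solute_selection(traj$frames[[1]])
  full <- traj_coords(traj)
  fit_to <- function(ref) {
    fitted <- full
    for (k in seq_len(dim(full)[3])) {
      sp <- superpose(full[, , k][which_sel(sel, nrow(full)), , drop = FALSE],
                      ref[which_sel(sel, nrow(full)), , drop = FALSE])
      fitted[, , k] <- apply_superposition(sp, full[, , k])
    }
    fitted
  }
  fitted <- fit_to(full[, , 1])
  avg <- apply(fitted, c(1, 2), mean)
  fitted <- fit_to(avg)
  avg <- apply(fitted, c(1, 2), mean)
  list(mean = avg, fitted = fitted)
}

#' Maximum RMSD of ensemble models to the ensemble average
#'
#' The summary convention used for NMR ensembles here: every model is
#' superposed onto the iterated ensemble-average structure (heavy atoms) and
#' the maximum over models of the resulting RMSD is reported.
#'
#' @param traj a \code{trajectory} (e.g. from \code{read_multimodel_pdb}).
#' @param sel fitting/deviation selection; default heavy solute atoms.
#' @return list with \code{max_rmsd}, \code{rmsd} (per model) and
#'   \code{mean} (average structure).
#' @export
ensemble_max_rmsd <- function(traj, sel = NULL) {
  if (is.null(sel)) sel <- heavy_solute_selection(traj$frames[[1]])
  ms <- mean_structure(traj, sel)
  idx <- which_sel(sel, nrow(traj$frames[[1]]$atoms))
  r <- vapply(seq_len(dim(ms$fitted)[3]), function(k)
    sqrt(mean(rowSums((ms$fitted[idx, , k] - ms$mean[idx, ]) ^ 2))), 0)
  list(max_rmsd = max(r), rmsd = r, mean = ms$mean)
}

#' Per-residue RMSF over backbone atoms
#'
#' Root-mean-square fluctuation per residue computed over the backbone atom
#' set P, OP1, OP2, O5', C5', O3' after superposing the whole trajectory on
#' its iterated mean structure.  5'-terminal residues lack the phosphate
#' group; they are computed from the available subset and flagged.
#'
#' @param traj a \code{trajectory}.
#' @param atoms atom names entering the fluctuation (default the backbone
#'   set above).
#' @return data.frame with \code{residue_index}, \code{rmsf} (Angstrom),
#'   \code{n_atoms} and \code{flag} (\code{"partial"} when some of the
#'   requested atoms are absent).
#' @export
rmsf_per_residue <- function(traj,
                             atoms = c("P", "OP1", "OP2", "O5'", "C5'", "O3'")) {
  at <- traj$frames[[1]]$atoms
  ms <- mean_structure(traj)
  res <- sort(unique(at$residue_index[!(at$klass %in% c("water", "ion"))]))
  out <- lapply(res, function(r) {
    idx <- which(at$residue_index == r & at$name %in% atoms)
    if (!length(idx))
      return(data.frame(residue_index = r, rmsf = NA_real_, n_atoms = 0L,
                        flag = "no-atoms"))
    dev2 <- 0
    for (k in seq_len(dim(ms$fitted)[3]))
      dev2 <- dev2 + rowSums((matrix(ms$fitted[idx, , k], ncol = 3) -
                              matrix(ms$mean[idx, ], ncol = 3))^2)
    data.frame(residue_index = r,
               rmsf = sqrt(mean(dev2 / dim(ms$fitted)[3])),
               n_atoms = length(idx),
               flag = if (length(idx) < length(atoms)) "partial" else "")
  })
  do.call(rbind, out)
}
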