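# iRED order parameters: isotropic reorientational eigenmode dynamics of a
# set of bond vectors.

# second Legendre polynomial Gram matrix via the rank-2 tensor embedding:
# P2(u.v) = w(u) . w(v) with the 6-component symmetric traceless map, so
# M = <P2(u_i . u_j)> accumulates as an outer product per frame.
p2_embedding <- function(U) {
  # U: n x 3 unit vectors
  x <- U[, 1]; y <- U[, 2]; z <- U[, 3]
  sqrt(3 / 2) * cbind(x * x, y * y, z * z,
                      sqrt(2) * x * y, sqrt(2) * x * z, sqrt(2) * y * z)
}

#' iRED order parameters from a set of unit-vector time series
#'
#' Builds the matrix M_ij = <P2(u_i . u_j)> over frames, diagonalizes it,
#' and computes S2_i = 1 - sum over all but the five largest eigenmodes of
#' lambda_m |m_i|^2.  The five discarded modes carry the collective
#' (tumbling-like) reorientation, matching the convention of the standard
#' trajectory-analysis utility.  Fewer than six vectors leave no internal
#' modes; in that case the direct <P2> plateau estimator is used instead
#' and the result is flagged.
#'
#' @param U array n_vectors x 3 x n_frames of (not necessarily normalized)
#'   bond vectors.
#' @return object of class \code{order_parameters}: list with \code{S2}
#'   (per vector), \code{eigenvalues}, \code{method} ("ired" or
#'   "direct-P2"), \code{n_frames}.
#' @export
ired_s2 <- function(U) {
  stopifnot(length(dim(U)) == 3, dim(U)[2] == 3)
  n <- dim(U)[1]; nf <- dim(U)[3]
  M <- matrix(0, n, n)
  W_mean <- matrix(0, n, 6)
  # frames are embedded in blocks so the Gram accumulation is one matrix
  # product per block
  block <- max(1L, min(nf, as.integer(2e6 / n)))
  k <- 1L
  while (k <= nf) {
    kk <- min(k + block - 1L, nf)
    Wb <- matrix(0, n, 6L * (kk - k + 1L))
    for (t in k:kk) {
      Uk <- matrix(U[, , t], n, 3)
      len <- sqrt(rowSums(Uk^2))
      if (any(len < 1e-9)) stop("zero-length bond vector in frame ", t)
      W <- p2_embedding(Uk / len)
      Wb[, (6L * (t - k) + 1L):(6L * (t - k + 1L))] <- W
      W_mean <- W_mean + W
    }
    M <- M + tcrossprod(Wb)
    k <- kk + 1L
  }
  # the embedding carries the trace part: w(u).w(v) = P2(u.v) + 1/2
  M <- M / nf - 0.5
  W_mean <- W_mean / nf
  # direct plateau estimator: S2_i = lim <P2(u(t).u(t'))> = |<w>|^2 - 1/2
  s2_direct <- rowSums(W_mean^2) - 0.5
  if (n < 6) {
    return(structure(list(S2 = pmin(1, pmax(0, s2_direct)),
                          eigenvalues = NULL, method = "direct-P2",
                          n_frames = nf,
                          flag = "fewer than 6 vectors; iRED undefined"),
                     class = "order_parameters"))
  }
  eg <- eigen(M, symmetric = TRUE)
  keep <- 6:n   # all but the 5 largest
  S2 <- 1 - colSums(t(eg$vectors[, keep, drop = FALSE]^2) *
                      eg$values[keep])
  structure(list(S2 = pmin(1, pmax(0, S2)), eigenvalues = eg$values,
                 method = "ired", n_frames = nf, flag = ""),
            class = "order_parameters")
}

#' @export
print.order_parameters <- function(x, ...) {
  cat(sprintf("order parameters (%s, %d frames): S2 in [%.3f, %.3f]\n",
              x$method, x$n_frames, min(x$S2), max(x$S2)))
  invisible(x)
}

#' C1'-H1' order parameters of a duplex trajectory
#'
#' Extracts the sugar C1'-H1' bond vector of every residue and runs
#' \code{\link{ired_s2}}.  The summary value excludes the terminal residue
#' of each strand, where end fraying dominates.
#'
#' @param traj a \code{trajectory} of classified frames.
#' @return the \code{order_parameters} object with an added data.frame
#'   \code{by_residue} and \code{min_internal} (minimum S2 over
#'   non-terminal residues).
#' @export
order_parameters_ired <- function(traj) {
  at <- traj$frames[[1]]$atoms
  solute <- !(at$klass %in% c("water", "ion"))
  res <- sort(unique(at$residue_index[solute]))
  ic1 <- vapply(res, function(r) atom_index(traj$frames[[1]], r, "C1'"), 0L)
  ih1 <- vapply(res, function(r) atom_index(traj$frames[[1]], r, "H1'"), 0L)
  nf <- length(traj$frames)
  U <- array(0, c(length(res), 3, nf))
  for (k in seq_len(nf)) {
    m <- frame_coords(traj$frames[[k]])
    U[, , k] <- m[ih1, , drop = FALSE] - m[ic1, , drop = FALSE]
  }
  out <- ired_s2(U)
  out$by_residue <- data.frame(residue_index = res, S2 = out$S2)
  # terminal residues: first and last of each strand under the 1..2N layout
  n2 <- length(res)
  term <- c(res[1], res[n2 / 2], res[n2 / 2 + 1], res[n2])
  out$min_internal <- min(out$S2[!res %in% term])
  out
}
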