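# Average-linkage clustering of trajectory frames on the pairwise-RMSD
# matrix, with the representative structure of the most populated cluster.

#' Pairwise RMSD matrix of a trajectory
#'
#' Heavy-atom RMSD after optimal per-pair superposition.
#'
#' @param traj a \code{trajectory}.
#' @param sel selection used for the fit (default heavy solute atoms).
#' @return a symmetric matrix of RMSDs (Angstrom).
#' @export
pairwise_rmsd <- function(traj, sel = NULL) {
  if (is.null(sel)) sel <- heavy_solute_selection(traj$frames[[1]])
  xs <- lapply(traj$frames, frame_coords, sel = sel)
  nf <- length(xs)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      D[i, j] <- D[j, i] <- superpose(xs[[j]], xs[[i]])$rmsd
    }
  }
  D
}

#' Average-linkage clustering of trajectory frames
#'
#' Agglomerative clustering (\code{stats::hclust}, method
#' \code{"average"}) on the pairwise heavy-atom RMSD matrix, cut at
#' \code{n_clusters}.  The representative structure is the coordinate
#' average of the most populated cluster, re-superposed and averaged once
#' more to remove the dependence on the initial frame.  Ties in cluster
#' population are broken towards the lowest cluster index.
#'
#' @param traj a \code{trajectory}.
#' @param n_clusters number of clusters (>= 1).
#' @param sel fitting selection (default heavy solute atoms).
#' @return object of class \code{cluster_result}: list with
#'   \code{assignments} (per frame), \code{populations},
#'   \code{representative} (a \code{conformation_frame}),
#'   \code{top_cluster} and the \code{hclust} tree.
#' @export
cluster_frames <- function(traj, n_clusters = 1, sel = NULL) {
  nf <- length(traj$frames)
  if (n_clusters < 1) stop("n_clusters must be at least 1")
  if (n_clusters > nf) stop("n_clusters exceeds the number of frames")
  if (n_clusters == 1) {
    # single cluster: the RMSD matrix is not needed
    assign <- rep(1L, nf)
    tree <- NULL
  } else {
    D <- pairwise_rmsd(traj, sel)
    tree <- stats::hclust(stats::as.dist(D), method = "average")
    assign <- stats::cutree(tree, k = n_clusters)
  }
  pops <- tabulate(assign, nbins = n_clusters)
  top <- which.max(pops)   # which.max takes the first (lowest index) on ties
  members <- which(assign == top)
  sub <- trajectory(traj$frames[members], dt = traj$dt)
  ms <- mean_structure(sub, sel)
  rep_frame <- set_frame_coords(traj$frames[[members[1]]], ms$mean)
  structure(list(assignments = assign, populations = pops,
                 representative = rep_frame, top_cluster = top,
                 tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("average-linkage clustering:", length(x$populations),
      "cluster(s), populations:", paste(x$populations, collapse = ", "),
      "\n")
  invisible(x)
}
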