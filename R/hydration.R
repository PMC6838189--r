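# Hydration analysis: hydrogen-bond detection, water bridges and lifetimes,
# radial distribution functions and water occupancy grids.

#' Hydrogen-bond geometric criteria
#'
#' A donor-H...acceptor triple is a hydrogen bond when the donor-acceptor
#' distance is at most \code{d_max} and the donor-H-acceptor angle is at
#' least \code{theta_min}.  Defaults: 3.0 A and 135 degrees.
#'
#' @param d_max donor-acceptor distance ceiling, Angstrom.
#' @param theta_min donor-hydrogen-acceptor angle floor, degrees.
#' @return object of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(d_max = 3.0, theta_min = 135.0) {
  if (d_max <= 0) stop("d_max must be positive")
  if (theta_min <= 0 || theta_min > 180)
    stop("theta_min must lie in (0, 180]")
  structure(list(d_max = d_max, theta_min = theta_min),
            class = "hbond_criteria")
}

# Donor (heavy, H) atom-name pairs per residue code; water handled apart.
SOLUTE_DONORS <- list(
  A = list(c("N6", "H61"), c("N6", "H62")),
  G = list(c("N1", "H1"), c("N2", "H21"), c("N2", "H22")),
  C = list(c("N4", "H41"), c("N4", "H42")),
  U = list(c("N3", "H3")),
  PSU = list(c("N3", "H3"), c("N1", "HN1")))

# Acceptor atom names on the solute; water O is always an acceptor.
SOLUTE_ACCEPTORS <- c("OP1", "OP2", "O5'", "O3'", "O2'", "O4'",
                      "O2", "O4", "O6", "N7", "N3", "N1")

#' Donor table of a frame
#'
#' Enumerates donor (heavy, hydrogen) index pairs: solute N-H donors known
#' for each residue code plus both hydrogens of every water.  Donors whose
#' hydrogen is missing from the frame are skipped with a warning.
#'
#' @param frame a classified \code{conformation_frame}.
#' @return data.frame with columns \code{donor} and \code{hydrogen} (row
#'   indices into the atom table).
#' @export
frame_donors <- function(frame) {
  at <- frame$atoms
  rows <- list()
  solute_res <- unique(at$residue_index[!(at$klass %in% c("water", "ion"))])
  for (r in solute_res) {
    code <- at$residue_code[at$residue_index == r][1]
    for (dh in SOLUTE_DONORS[[code]]) {
      di <- which(at$residue_index == r & at$name == dh[1])
      hi <- which(at$residue_index == r & at$name == dh[2])
      if (length(di) == 1 && length(hi) == 1) {
        rows[[length(rows) + 1]] <- c(di, hi)
      } else if (length(di) == 1) {
        warning("donor ", dh[1], " of residue ", r,
                " has no attached hydrogen; skipped")
      }
    }
  }
  wat <- which(at$klass == "water" & at$name == "O")
  for (wo in wat) {
    for (hn in c("H1", "H2")) {
      hi <- which(at$klass == "water" & at$name == hn &
                  at$residue_index == at$residue_index[wo])
      if (length(hi) == 1) rows[[length(rows) + 1]] <- c(wo, hi)
    }
  }
  out <- do.call(rbind, rows)
  data.frame(donor = out[, 1], hydrogen = out[, 2])
}

#' Acceptor indices of a frame
#' @param frame a classified \code{conformation_frame}.
#' @return integer vector of acceptor atom rows (solute O/N acceptors and
#'   water oxygens).
#' @export
frame_acceptors <- function(frame) {
  at <- frame$atoms
  sol <- which(!(at$klass %in% c("water", "ion")) &
               at$name %in% SOLUTE_ACCEPTORS)
  wat <- which(at$klass == "water" & at$name == "O")
  c(sol, wat)
}

#' Detect hydrogen bonds in one frame
#'
#' Reports every (donor, hydrogen, acceptor) triple satisfying the
#' criteria.  Donor and acceptor belonging to the same residue are allowed
#' (intra-residue bonds are part of the analysis); self-pairs
#' (donor == acceptor) are excluded.
#'
#' @param frame a classified \code{conformation_frame}.
#' @param donors data.frame as from \code{\link{frame_donors}}.
#' @param acceptors integer vector as from \code{\link{frame_acceptors}}.
#' @param criteria an \code{\link{hbond_criteria}} object.
#' @return data.frame with \code{donor}, \code{hydrogen}, \code{acceptor}
#'   (atom row indices), \code{distance} (A) and \code{angle} (deg).
#' @export
detect_hbonds <- function(frame, donors = frame_donors(frame),
                          acceptors = frame_acceptors(frame),
                          criteria = hbond_criteria()) {
  xyz <- frame_coords(frame)
  out <- vector("list", nrow(donors))
  for (k in seq_len(nrow(donors))) {
    di <- donors$donor[k]; hi <- donors$hydrogen[k]
    acc <- acceptors[acceptors != di]
    d <- sqrt(rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[di, ])^2))
    near <- which(d <= criteria$d_max)
    if (!length(near)) next
    ang <- vapply(acc[near], function(a)
      angle3(xyz[di, ], xyz[hi, ], xyz[a, ]), 0)
    ok <- ang >= criteria$theta_min
    if (!any(ok)) next
    out[[k]] <- data.frame(donor = di, hydrogen = hi,
                           acceptor = acc[near][ok],
                           distance = d[near][ok], angle = ang[ok])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric())
  res
}

# Resolve a site spec c(residue, atom_name) into its hydrogen-bonding role.
# Returns list(kind = "donor"/"acceptor"/"inert", heavy, hydrogen).
site_role <- function(frame, site) {
  r <- as.integer(site[[1]]); nm <- as.character(site[[2]])
  at <- frame$atoms
  code <- at$residue_code[at$residue_index == r][1]
  # site named by its proton (e.g. HN1) -> donor through the parent heavy atom
  if (nm %in% c("HN1", "H3", "H1", "H21", "H22", "H41", "H42", "H61", "H62")) {
    pairs <- SOLUTE_DONORS[[code]]
    hit <- Filter(function(p) p[2] == nm, pairs)
    if (length(hit))
      return(list(kind = "donor",
                  heavy = atom_index(frame, r, hit[[1]][1]),
                  hydrogen = atom_index(frame, r, nm)))
    return(list(kind = "inert", heavy = atom_index(frame, r, nm)))
  }
  if (nm %in% SOLUTE_ACCEPTORS)
    return(list(kind = "acceptor", heavy = atom_index(frame, r, nm)))
  pairs <- Filter(function(p) p[1] == nm, SOLUTE_DONORS[[code]])
  if (length(pairs))
    return(list(kind = "donor", heavy = atom_index(frame, r, nm),
                hydrogen = atom_index(frame, r, pairs[[1]][2])))
  list(kind = "inert", heavy = atom_index(frame, r, nm))
}

# Water residue indices H-bonded to a site in one frame (site as donor to
# water O, or water H donating to the site acceptor).
waters_bonded_to_site <- function(frame, role, criteria) {
  at <- frame$atoms
  xyz <- frame_coords(frame)
  wo <- which(at$klass == "water" & at$name == "O")
  if (!length(wo) || role$kind == "inert") return(integer())
  res <- integer()
  if (role$kind == "donor") {
    d <- sqrt(rowSums(sweep(xyz[wo, , drop = FALSE], 2, xyz[role$heavy, ])^2))
    near <- which(d <= criteria$d_max)
    for (k in near) {
      if (angle3(xyz[role$heavy, ], xyz[role$hydrogen, ], xyz[wo[k], ]) >=
          criteria$theta_min)
        res <- c(res, at$residue_index[wo[k]])
    }
  } else {
    for (k in seq_along(wo)) {
      dwa <- vnorm(xyz[wo[k], ] - xyz[role$heavy, ])
      if (dwa > criteria$d_max) next
      wres <- at$residue_index[wo[k]]
      for (hn in c("H1", "H2")) {
        hi <- which(at$residue_index == wres & at$name == hn)
        if (length(hi) == 1 &&
            angle3(xyz[wo[k], ], xyz[hi, ], xyz[role$heavy, ]) >=
            criteria$theta_min) {
          res <- c(res, wres)
          break
        }
      }
    }
  }
  unique(res)
}

# water-water hydrogen bond (either donates) between two water residues
waters_mutually_bonded <- function(frame, wres1, wres2, criteria) {
  xyz <- frame_coords(frame)
  at <- frame$atoms
  o1 <- which(at$residue_index == wres1 & at$name == "O")
  o2 <- which(at$residue_index == wres2 & at$name == "O")
  if (vnorm(xyz[o1, ] - xyz[o2, ]) > criteria$d_max) return(FALSE)
  for (pair in list(c(wres1, o1, o2), c(wres2, o2, o1))) {
    for (hn in c("H1", "H2")) {
      hi <- which(at$residue_index == pair[1] & at$name == hn)
      if (length(hi) == 1 &&
          angle3(xyz[pair[2], ], xyz[hi, ], xyz[pair[3], ]) >=
          criteria$theta_min)
        return(TRUE)
    }
  }
  FALSE
}

#' Per-frame presence of a water bridge between two sites
#'
#' @param traj a \code{trajectory} with waters.
#' @param site_a,site_b site specifications \code{c(residue_index, atom)};
#'   e.g. \code{c(5, "HN1")} (donor via N1) or \code{c(5, "OP2")}
#'   (acceptor).
#' @param criteria an \code{\link{hbond_criteria}}.
#' @param chain_order 1 for a single bridging water bonded to both sites in
#'   the same frame, 2 for a chain water_a - water_b with water_a bonded to
#'   site_a, water_b to site_b and the two waters hydrogen-bonded.
#' @return logical vector, one entry per frame.
#' @export
bridge_series <- function(traj, site_a, site_b,
                          criteria = hbond_criteria(), chain_order = 1) {
  if (identical(as.character(site_a), as.character(site_b)))
    stop("site_a and site_b must differ")
  if (!chain_order %in% c(1, 2)) stop("chain_order must be 1 or 2")
  vapply(traj$frames, function(fr) {
    ra <- site_role(fr, site_a)
    rb <- site_role(fr, site_b)
    wa <- waters_bonded_to_site(fr, ra, criteria)
    if (!length(wa)) return(FALSE)
    wb <- waters_bonded_to_site(fr, rb, criteria)
    if (!length(wb)) return(FALSE)
    if (chain_order == 1) return(length(intersect(wa, wb)) > 0)
    for (w1 in wa) for (w2 in wb) {
      if (w1 != w2 && waters_mutually_bonded(fr, w1, w2, criteria))
        return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Water-bridge occupancy and lifetime statistics
#'
#' Occupancy is the percentage of frames in which at least one qualifying
#' bridge exists (the bridging water's identity may change between frames).
#' The mean lifetime is the average length of maximal runs of consecutive
#' bridged frames times the frame spacing, with zero gap tolerance.
#'
#' @inheritParams bridge_series
#' @param label optional row label, e.g. \code{"OP2(5)-W-HN1(5)"}.
#' @return object of class \code{bridge_statistics}: list with
#'   \code{label}, \code{occupancy} (percent), \code{lifetime_ns},
#'   \code{chain_order}, \code{n_frames} and the presence \code{series}.
#' @export
bridge_occupancy <- function(traj, site_a, site_b,
                             criteria = hbond_criteria(), chain_order = 1,
                             label = NULL) {
  series <- bridge_series(traj, site_a, site_b, criteria, chain_order)
  if (is.null(label))
    label <- sprintf("%s(%s)-W-%s(%s)", site_b[[2]], site_b[[1]],
                     site_a[[2]], site_a[[1]])
  structure(list(label = label,
                 occupancy = 100 * mean(series),
                 lifetime_ns = lifetime_from_series(series, traj$dt),
                 chain_order = chain_order,
                 n_frames = length(series),
                 series = series),
            class = "bridge_statistics")
}

#' @export
print.bridge_statistics <- function(x, ...) {
  cat(sprintf("%s: occupancy %.1f%% over %d frames, mean lifetime %.3f ns (chain order %d)\n",
              x$label, x$occupancy, x$n_frames, x$lifetime_ns, x$chain_order))
  invisible(x)
}

#' Mean continuous lifetime of a presence series
#'
#' @param series logical vector (bond present per frame).
#' @param dt frame spacing, ps.
#' @return mean run length times dt, in ns; 0 if never present.
#' @export
lifetime_from_series <- function(series, dt) {
  if (!any(series)) return(0)
  r <- rle(series)
  mean(r$lengths[r$values]) * dt / 1000
}

#' Presence series of a site - water hydrogen bond
#'
#' TRUE for frames in which the site is hydrogen-bonded to at least one
#' water (any water; identity may change).
#'
#' @inheritParams bridge_series
#' @param site site specification \code{c(residue, atom)}.
#' @return logical vector over frames.
#' @export
hbond_series <- function(traj, site, criteria = hbond_criteria()) {
  vapply(traj$frames, function(fr) {
    role <- site_role(fr, site)
    length(waters_bonded_to_site(fr, role, criteria)) > 0
  }, logical(1))
}

#' Mean lifetime of a site-water hydrogen bond along a trajectory
#' @inheritParams hbond_series
#' @return list with \code{lifetime_ns} and \code{occupancy} (percent).
#' @export
hbond_lifetime <- function(traj, site, criteria = hbond_criteria()) {
  s <- hbond_series(traj, site, criteria)
  list(lifetime_ns = lifetime_from_series(s, traj$dt),
       occupancy = 100 * mean(s))
}

#' Radial distribution function of water oxygens around a reference site
#'
#' g(r) of water oxygens around a fixed atom or the geometric centre of two
#' atoms, averaged over frames.  With a box on the frames the bulk density
#' rho = N_water / V normalizes the profile; otherwise the profile is
#' self-normalized by its mean beyond \code{tail_from} (mode recorded in
#' the result).  Shell volumes are exact, so the integral
#' sum g(r) rho V_shell recovers the water count within the sampled range.
#'
#' @param traj a \code{trajectory} whose frames contain waters.
#' @param ref_spec list of one or two \code{c(residue, atom)} sites, or a
#'   numeric 3-vector giving a fixed reference point in the lab frame.
#' @param bin bin width, Angstrom (default 0.05).
#' @param r_max maximum radius, Angstrom.
#' @param tail_from self-normalization start radius when no box is present.
#' @return object of class \code{rdf_profile}: data.frame-like list with
#'   \code{r} (bin centres), \code{g}, \code{counts}, plus normalization
#'   metadata.
#' @export
rdf <- function(traj, ref_spec, bin = 0.05, r_max = 10, tail_from = 0.75 * r_max) {
  if (bin <= 0) stop("bin must be positive")
  fr1 <- traj$frames[[1]]
  at <- fr1$atoms
  wo <- which(at$klass == "water" & at$name == "O")
  if (!length(wo)) stop("no water oxygens in trajectory")
  fixed_point <- is.numeric(ref_spec) && length(ref_spec) == 3
  edges <- seq(0, r_max, by = bin)
  counts <- numeric(length(edges) - 1)
  for (fr in traj$frames) {
    xyz <- frame_coords(fr)
    centre <- if (fixed_point) as.numeric(ref_spec) else {
      refs <- vapply(ref_spec, function(s)
        xyz[atom_index(fr, as.integer(s[[1]]), as.character(s[[2]])), ],
        numeric(3))
      rowMeans(matrix(refs, nrow = 3))
    }
    d <- sqrt(rowSums(sweep(xyz[wo, , drop = FALSE], 2, centre)^2))
    counts <- counts + tabulate(findInterval(d[d < r_max], edges),
                                nbins = length(counts))
  }
  nf <- length(traj$frames)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  box <- fr1$box
  if (!is.null(box)) {
    rho <- length(wo) / prod(box)
    g <- counts / nf / (rho * shell_vol)
    mode <- "box-density"
  } else {
    g_raw <- counts / nf / shell_vol
    tail_idx <- edges[-1] > tail_from
    scale <- mean(g_raw[tail_idx & g_raw > 0])
    if (!is.finite(scale) || scale <= 0) {
      # no far-shell population to normalize against: report raw density
      scale <- 1
      mode <- "unnormalized-counts"
    } else {
      mode <- "self-normalized"
    }
    g <- g_raw / scale
    rho <- scale
  }
  structure(list(r = (edges[-1] + edges[-length(edges)]) / 2, g = g,
                 counts = counts / nf, bin = bin, r_max = r_max,
                 n_target = length(wo), density = rho,
                 normalization = mode),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  pk <- x$r[which.max(x$g)]
  cat(sprintf("RDF: %d bins to %.1f A (%s), max g = %.2f at %.3f A\n",
              length(x$r), x$r_max, x$normalization, max(x$g), pk))
  invisible(x)
}

#' Water-oxygen occupancy grid
#'
#' Fraction of frames with at least one water oxygen per voxel of a regular
#' grid.  Frames are assumed already superposed on a common reference (the
#' synthetic generators keep the solute fixed; for other input superpose
#' first with \code{\link{mean_structure}}).
#'
#' @param traj a \code{trajectory} with waters.
#' @param spacing voxel edge, Angstrom (default 0.5).
#' @param origin grid origin; default covers all water positions.
#' @param dims integer 3-vector of voxel counts; default from coverage.
#' @return object of class \code{occupancy_grid}: list with \code{origin},
#'   \code{spacing}, \code{counts} (3D array of occupancy fractions).
#' @export
occupancy_grid <- function(traj, spacing = 0.5, origin = NULL, dims = NULL) {
  if (spacing <= 0) stop("spacing must be positive")
  at <- traj$frames[[1]]$atoms
  wo_sel <- at$klass == "water" & at$name == "O"
  allw <- do.call(rbind, lapply(traj$frames, frame_coords, sel = wo_sel))
  if (is.null(origin)) origin <- apply(allw, 2, min) - spacing / 2
  if (is.null(dims))
    dims <- pmax(1L, as.integer(ceiling((apply(allw, 2, max) - origin) /
                                          spacing)) + 1L)
  counts <- array(0L, dims)
  for (fr in traj$frames) {
    w <- frame_coords(fr, wo_sel)
    vox <- floor(sweep(w, 2, origin) / spacing) + 1
    inside <- vox[, 1] >= 1 & vox[, 2] >= 1 & vox[, 3] >= 1 &
      vox[, 1] <= dims[1] & vox[, 2] <= dims[2] & vox[, 3] <= dims[3]
    vox <- unique(vox[inside, , drop = FALSE])
    if (nrow(vox)) counts[vox] <- counts[vox] + 1L
  }
  structure(list(origin = origin, spacing = spacing,
                 counts = counts / length(traj$frames)),
            class = "occupancy_grid")
}

#' Difference of two occupancy grids (modified minus reference)
#' @param a,b \code{occupancy_grid} objects on identical grids.
#' @return an \code{occupancy_grid} of the voxel-wise difference.
#' @export
grid_difference <- function(a, b) {
  if (!all(dim(a$counts) == dim(b$counts)) ||
      max(abs(a$origin - b$origin)) > 1e-9 || a$spacing != b$spacing)
    stop("grids are not congruent")
  structure(list(origin = a$origin, spacing = a$spacing,
                 counts = a$counts - b$counts),
            class = "occupancy_grid")
}

#' Write an occupancy grid as an OpenDX-style volumetric text file
#' @param grid an \code{occupancy_grid}.
#' @param path output file.
#' @export
write_opendx <- function(grid, path) {
  d <- dim(grid$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX order: z fastest
  v <- numeric(prod(d))
  k <- 1
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v[k:(k + d[3] - 1)] <- grid$counts[i, j, ]
    k <- k + d[3]
  }
  writeLines(paste(formatC(v, format = "g"), collapse = "\n"), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(NULL)
}
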