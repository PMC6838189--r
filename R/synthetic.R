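# Synthetic dynamics and hydration: Gaussian pseudo-trajectories, explicit
# bridging-water placement around pseudouridine, and bulk solvation.
#
# None of this is molecular dynamics: thermal motion is emulated by
# uncorrelated isotropic Gaussian displacements, which is sufficient for the
# geometric and counting statistics computed downstream, and bridging waters
# are placed by construction so that the hydration detectors can be
# validated in a closed loop.

#' Gaussian perturbation specification
#'
#' @param sigma per-atom isotropic Gaussian displacement, Angstrom (keep
#'   well below bond lengths; values up to 0.3 are sensible).
#' @param n_frames number of frames to generate.
#' @param dt frame spacing, ps.
#' @param seed integer seed; the same spec always yields the same frames.
#' @param keep_first if TRUE frame 1 is the unperturbed input.
#' @return object of class \code{perturbation_spec}.
#' @export
perturbation_spec <- function(sigma = 0.2, n_frames = 100, dt = 10,
                              seed = 1, keep_first = FALSE) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (n_frames < 1) stop("n_frames must be at least 1")
  if (sigma > 0.3)
    warning("sigma above 0.3 A approaches bond-length scale")
  structure(list(sigma = sigma, n_frames = as.integer(n_frames), dt = dt,
                 seed = as.integer(seed), keep_first = keep_first),
            class = "perturbation_spec")
}

#' Thermally perturbed pseudo-trajectory
#'
#' Adds i.i.d. isotropic Gaussian displacements to every atom of the input
#' frame, independently per frame.  With displacement sigma the expected
#' per-atom RMSF is sigma * sqrt(3).
#'
#' @param frame a \code{conformation_frame}.
#' @param spec a \code{perturbation_spec}.
#' @return a \code{trajectory} of \code{spec$n_frames} frames.
#' @export
perturb_trajectory <- function(frame, spec = perturbation_spec()) {
  stopifnot(inherits(spec, "perturbation_spec"))
  base <- frame_coords(frame)
  n <- nrow(base)
  frames <- vector("list", spec$n_frames)
  rng <- local_rng(spec$seed)
  for (k in seq_len(spec$n_frames)) {
    noise <- if (spec$sigma == 0 || (spec$keep_first && k == 1)) 0 else
      matrix(rng$norm(3 * n, sd = spec$sigma), n, 3)
    fr <- set_frame_coords(frame, base + noise)
    fr$time <- (k - 1) * spec$dt
    frames[[k]] <- fr
  }
  trajectory(frames, dt = spec$dt)
}

# Deterministic RNG stream isolated from the global one
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  run <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = function(n, sd = 1) run(stats::rnorm, n, 0, sd),
       unif = function(n, min = 0, max = 1) run(stats::runif, n, min, max),
       sample = function(x, size) run(sample, x, size))
}

# TIP3P-like internal geometry: one oxygen, two hydrogens
WATER_OH <- 0.9572
WATER_HOH <- 104.52

# Build one water with O at `o`, first H towards `toward1`, second H in the
# plane spanned with `toward2` (or an arbitrary perpendicular).
make_water <- function(o, toward1, toward2 = NULL) {
  u1 <- unitv(toward1 - o)
  ref <- if (is.null(toward2)) {
    p <- cross3(u1, c(0, 0, 1))
    if (vnorm(p) < 1e-6) p <- cross3(u1, c(0, 1, 0))
    p
  } else toward2 - o
  perp <- ref - sum(ref * u1) * u1
  perp <- if (vnorm(perp) < 1e-8) unitv(cross3(u1, c(1, 0, 0))) else unitv(perp)
  if (is.null(toward2)) {
    h1 <- o + WATER_OH * u1
    u2 <- cos(deg2rad(WATER_HOH)) * u1 + sin(deg2rad(WATER_HOH)) * perp
    h2 <- o + WATER_OH * u2
  } else {
    # split the H-O-H angle symmetrically between the two target directions
    u2t <- unitv(toward2 - o)
    ang <- angle3(o + u1, o, o + u2t)
    excess <- (ang - WATER_HOH) / 2
    ax <- cross3(u1, u2t)
    if (vnorm(ax) < 1e-8) ax <- perp
    h1 <- o + WATER_OH * as.vector(rot_about_axis(ax, excess) %*% u1)
    h2 <- o + WATER_OH * as.vector(rot_about_axis(ax, -excess) %*% u2t)
  }
  m <- rbind(O = o, H1 = h1, H2 = h2)
  m
}

water_atoms_df <- function(olist, start_index) {
  rows <- lapply(seq_along(olist), function(k) {
    m <- olist[[k]]
    data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
               residue_index = start_index + k - 1L, residue_code = "HOH",
               klass = "water", x = m[, 1], y = m[, 2], z = m[, 3],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Deterministic placement of a bridging-water oxygen between a donor
# (heavy atom dn with proton h) and an acceptor position acc.
bridge_oxygen <- function(dn, h, acc, clash_xyz) {
  f <- function(o) {
    (vnorm(o - dn) - 2.85)^2 + (vnorm(o - acc) - 2.75)^2 +
      0.02 * max(0, 155 - angle3(dn, h, o))^2 +
      5 * sum(pmax(0, 2.4 - sqrt(rowSums(sweep(clash_xyz, 2, o)^2)))^2)
  }
  start <- h + 1.9 * unitv(h - dn)
  start <- (start + acc + 1e-3) / 2 + 0.5 * unitv(start - acc)
  o <- stats::optim(start, f, method = "BFGS",
                    control = list(maxit = 300, reltol = 1e-12))
  o$par
}

#' Place bridging waters around the modified residue
#'
#' Generates \code{n_frames} copies of the input frame with explicit waters
#' arranged so that a chosen fraction of frames contains the requested
#' bridge:
#' \describe{
#'   \item{intra_bridge}{one water simultaneously accepting from HN1 and
#'     donating to OP2 of the same residue — the intra-residue bridge
#'     characteristic of pseudouridine.}
#'   \item{two_water_chain}{the intra-residue water additionally donates to
#'     a second water that is hydrogen-bonded to OP2 of the 5'-neighbouring
#'     residue.}
#'   \item{single_inter_bridge}{one water attempting to bridge HN1 and the
#'     5'-neighbouring OP2 directly; if those sites are more than 5.4 A
#'     apart (as in a regular helix) this is geometrically strained — a
#'     warning is emitted and the water is placed best-effort.}
#' }
#' In the remaining frames the waters are parked several Angstrom away from
#' the sites so no hydrogen-bond bridge is possible.  With \code{jitter = 0}
#' the constructed bridges satisfy the default \code{\link{hbond_criteria}}
#' exactly, closing the loop between generator and detector.
#'
#' @param frame a classified \code{conformation_frame} (typically from
#'   \code{\link{build_aform_duplex}}).
#' @param mode \code{"intra_bridge"}, \code{"two_water_chain"} or
#'   \code{"single_inter_bridge"}.
#' @param residue index of the pseudouridine (or, as a negative control, a
#'   uridine, whose C-H edge cannot donate — detectors then report zero).
#' @param n_frames number of frames.
#' @param occupancy_fraction fraction of frames carrying the bridge.
#' @param jitter Gaussian displacement (A) applied to the water positions in
#'   bridged frames.
#' @param seed integer seed.
#' @param dt frame spacing, ps.
#' @return a \code{trajectory} (solute static, waters moving).
#' @export
place_bridge_waters <- function(frame, mode = c("intra_bridge",
                                                "two_water_chain",
                                                "single_inter_bridge"),
                                residue, n_frames = 100,
                                occupancy_fraction = 1, jitter = 0,
                                seed = 1, dt = 10) {
  mode <- match.arg(mode)
  if (occupancy_fraction < 0 || occupancy_fraction > 1)
    stop("occupancy_fraction must lie in [0, 1]")
  at <- frame$atoms
  code <- at$residue_code[at$residue_index == residue][1]
  if (!code %in% c("PSU", "U"))
    stop("bridge construction expects a PSU (or control U) residue")
  is_psu <- code == "PSU"
  dn <- atom_xyz(frame, residue, if (is_psu) "N1" else "C5")
  h <- atom_xyz(frame, residue, if (is_psu) "HN1" else "H5")
  op2_same <- atom_xyz(frame, residue, "OP2")
  op2_prev <- atom_xyz(frame, residue - 1, "OP2")
  solute_xyz <- frame_coords(frame)[heavy_solute_selection(frame), ]

  if (mode == "single_inter_bridge" && vnorm(h - op2_prev) > 5.4)
    warning(sprintf(
      "HN1-OP2(5') distance %.2f A exceeds 5.4 A: single water bridge is geometrically strained",
      vnorm(h - op2_prev)))

  acc1 <- if (mode == "single_inter_bridge") op2_prev else op2_same
  o1 <- bridge_oxygen(dn, h, acc1, solute_xyz)
  waters_on <- list()
  if (mode == "two_water_chain") {
    f2 <- function(o) {
      (vnorm(o - o1) - 2.80)^2 + (vnorm(o - op2_prev) - 2.75)^2 +
        5 * sum(pmax(0, 2.4 - sqrt(rowSums(sweep(solute_xyz, 2, o)^2)))^2)
    }
    o2 <- stats::optim((o1 + op2_prev) / 2 +
                         1.2 * unitv(cross3(op2_prev - o1, dn - o1)),
                       f2, method = "BFGS",
                       control = list(maxit = 300, reltol = 1e-12))$par
    waters_on[[1]] <- make_water(o1, acc1, o2)
    waters_on[[2]] <- make_water(o2, op2_prev)
  } else {
    waters_on[[1]] <- make_water(o1, acc1)
  }
  # parking spot for bridge-off frames: out along the major groove normal
  away_dir <- unitv(h - dn)
  park <- function(w, k) sweep(w, 2, (8 + 1.5 * k) * away_dir, "+")
  waters_off <- lapply(seq_along(waters_on),
                       function(k) park(waters_on[[k]], k))

  n_on <- round(occupancy_fraction * n_frames)
  rng <- local_rng(seed)
  on_frames <- if (n_on == 0) integer() else
    sort(rng$sample(seq_len(n_frames), n_on))
  start_idx <- max(at$residue_index) + 1L
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    w <- if (k %in% on_frames) waters_on else waters_off
    if (jitter > 0) {
      w <- lapply(w, function(m)
        m + matrix(rep(rng$norm(3, sd = jitter), each = 3), 3, 3))
    }
    at_k <- rbind(at, water_atoms_df(w, start_idx))
    fr <- conformation_frame(at_k, box = frame$box, time = (k - 1) * dt)
    frames[[k]] <- fr
  }
  trajectory(frames, dt = dt)
}

#' Add uniformly random bulk waters to a frame
#'
#' Water oxygens are drawn uniformly in an orthorhombic box centred on the
#' solute centroid (or the origin for an empty frame), rejecting positions
#' within \code{min_dist} of any solute atom.  Water orientations are
#' random.  The box is stored on the frame for RDF normalization.
#'
#' @param frame a \code{conformation_frame} (may have zero atoms).
#' @param n_waters number of waters to add.
#' @param box numeric 3-vector of box edge lengths, Angstrom.
#' @param min_dist exclusion distance from solute atoms (>= 1.5 A).
#' @param seed integer seed.
#' @return the frame with waters appended and \code{box} set.
#' @export
solvate_random <- function(frame, n_waters, box, min_dist = 2.5, seed = 1) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(box > 0))
  if (min_dist < 1.5) stop("min_dist must be at least 1.5 A")
  if (n_waters == 0) return(frame)
  at <- frame$atoms
  centre <- if (nrow(at)) colMeans(frame_coords(frame)) else c(0, 0, 0)
  solute_xyz <- if (nrow(at)) frame_coords(frame) else
    matrix(numeric(), 0, 3)
  rng <- local_rng(seed)
  placed <- matrix(NA_real_, n_waters, 3)
  got <- 0
  tries <- 0
  max_tries <- 1000 * n_waters + 1000
  while (got < n_waters) {
    need <- n_waters - got
    tries <- tries + need
    if (tries > max_tries)
      stop("could not place waters outside min_dist after bounded retries")
    cand <- sweep(matrix(rng$unif(3 * need), need, 3) - 0.5, 2, box, "*")
    cand <- sweep(cand, 2, centre, "+")
    ok <- rep(TRUE, need)
    if (nrow(solute_xyz)) {
      for (k in seq_len(need)) {
        d2 <- rowSums(sweep(solute_xyz, 2, cand[k, ])^2)
        ok[k] <- min(d2) >= min_dist^2
      }
    }
    n_ok <- sum(ok)
    if (n_ok) {
      placed[(got + 1):(got + n_ok), ] <- cand[ok, , drop = FALSE]
      got <- got + n_ok
    }
  }
  # vectorized random orientations at TIP3P internal geometry
  u1 <- matrix(rng$norm(3 * n_waters), n_waters, 3)
  u1 <- u1 / sqrt(rowSums(u1^2))
  ref <- matrix(rng$norm(3 * n_waters), n_waters, 3)
  perp <- ref - rowSums(ref * u1) * u1
  perp <- perp / sqrt(rowSums(perp^2))
  th <- deg2rad(WATER_HOH)
  u2 <- cos(th) * u1 + sin(th) * perp
  h1 <- placed + WATER_OH * u1
  h2 <- placed + WATER_OH * u2
  start_idx <- if (nrow(at)) max(at$residue_index) + 1L else 1L
  ord <- rep(seq_len(n_waters), each = 3)
  xyz <- matrix(0, 3 * n_waters, 3)
  xyz[seq(1, 3 * n_waters, 3), ] <- placed
  xyz[seq(2, 3 * n_waters, 3), ] <- h1
  xyz[seq(3, 3 * n_waters, 3), ] <- h2
  wat <- data.frame(name = rep(c("O", "H1", "H2"), n_waters),
                    element = rep(c("O", "H", "H"), n_waters),
                    residue_index = start_idx + ord - 1L,
                    residue_code = "HOH", klass = "water",
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  conformation_frame(rbind(at, wat), box = box, time = frame$time)
}
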