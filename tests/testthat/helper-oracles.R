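# Independent oracles and small fixture builders used across the suite.

# Horn's quaternion method for optimal superposition: an implementation
# independent of the SVD route used by superpose().
quaternion_superpose <- function(X, Y) {
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  S <- crossprod(Xc, Yc)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  eg <- eigen(K, symmetric = TRUE)
  q <- eg$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fitted <- sweep(Xc %*% t(R), 2, yc, "+")   # rotation acts as y = R x
  list(rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

# Naive O(n^2) double-loop nonbonded energy between two fragments.
pair_energy_oracle <- function(frag_i, frag_j, params) {
  key <- paste(params$residue_code, params$atom_name)
  get_p <- function(code, nm) params[match(paste(code, nm), key), ]
  k <- attr(params, "coulomb_constant")
  elec <- 0; vdw <- 0
  for (a in seq_along(frag_i$names)) {
    pa <- get_p(frag_i$code, frag_i$names[a])
    for (b in seq_along(frag_j$names)) {
      pb <- get_p(frag_j$code, frag_j$names[b])
      r <- sqrt(sum((frag_i$xyz[a, ] - frag_j$xyz[b, ])^2))
      elec <- elec + k * pa$charge * pb$charge / r
      sig <- (pa$sigma + pb$sigma) / 2
      eps <- sqrt(pa$epsilon * pb$epsilon)
      vdw <- vdw + 4 * eps * ((sig / r)^12 - (sig / r)^6)
    }
  }
  c(elec = elec, vdw = vdw, total = elec + vdw)
}

# All-triples brute-force hydrogen-bond detector.
hbond_oracle <- function(frame, donors, acceptors, criteria) {
  xyz <- frame_coords(frame)
  hits <- list()
  for (k in seq_len(nrow(donors))) {
    for (a in acceptors) {
      if (a == donors$donor[k]) next
      d <- sqrt(sum((xyz[donors$donor[k], ] - xyz[a, ])^2))
      if (d > criteria$d_max) next
      v1 <- xyz[donors$donor[k], ] - xyz[donors$hydrogen[k], ]
      v2 <- xyz[a, ] - xyz[donors$hydrogen[k], ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= criteria$theta_min)
        hits[[length(hits) + 1]] <- c(donors$donor[k], donors$hydrogen[k], a)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) matrix(integer(), 0, 3) else out[order(out[, 1], out[, 3]), , drop = FALSE]
}

# Least-squares pseudorotation fit: finds (P, tau_m) minimizing the misfit
# to the five observed torsions, independent of the closed-form relation.
pucker_fit_oracle <- function(nu) {
  obj <- function(par) {
    P <- par[1]; taum <- par[2]
    sum((nu - taum * cos((P + 144 * (0:4 - 2)) * pi / 180))^2)
  }
  best <- NULL
  for (P0 in seq(0, 330, by = 30)) {
    o <- stats::optim(c(P0, 40), obj, method = "BFGS",
                      control = list(reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  P <- best$par[1] %% 360
  taum <- best$par[2]
  if (taum < 0) { taum <- -taum; P <- (P + 180) %% 360 }
  list(phase = P, amplitude = taum)
}

# Random planar "base-like" fragment with parameter entries drawn from the
# uracil table (names recycled), for energy oracle tests.
random_fragment <- function(n = 12, centre = c(0, 0, 0), code = "U") {
  nm <- base_atom_names(code)
  nm <- rep(nm, length.out = n)
  xyz <- matrix(stats::rnorm(3 * n, sd = 2), n, 3)
  xyz <- sweep(xyz, 2, centre, "+")
  list(code = code, names = nm, xyz = xyz)
}

# Tiny custom force field with one atom type, for closed-form checks.
point_forcefield <- function(charge = 0.5, sigma = 0, epsilon = 0) {
  tab <- data.frame(residue_code = "X", atom_name = "Q",
                    charge = charge, sigma = sigma, epsilon = epsilon)
  structure(tab, coulomb_constant = 332.0637,
            combining_rule = "lorentz-berthelot",
            psu_charges = "surrogate",
            class = c("forcefield_parameters", "data.frame"))
}

point_fragment <- function(xyz) {
  xyz <- rbind(xyz)
  list(code = "X", names = rep("Q", nrow(xyz)), xyz = xyz)
}

# Minimal frame containing explicit atoms (data.frame shortcut).
make_frame <- function(name, element, residue_index, residue_code, klass,
                       xyz, box = NULL) {
  conformation_frame(data.frame(
    name = name, element = element, residue_index = residue_index,
    residue_code = residue_code, klass = klass,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), box = box)
}

empty_frame <- function() {
  conformation_frame(data.frame(
    name = character(), element = character(), residue_index = integer(),
    residue_code = character(), klass = character(),
    x = numeric(), y = numeric(), z = numeric()))
}

# Uniform sampling inside a cone of semi-angle theta about given axes;
# returns an n x 3 x n_frames array.
cone_vectors <- function(axes, theta_deg, n_frames) {
  n <- nrow(axes)
  th <- theta_deg * pi / 180
  U <- array(0, c(n, 3, n_frames))
  for (i in seq_len(n)) {
    z <- axes[i, ]
    ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * z) * z; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(z[2] * e1[3] - z[3] * e1[2],
            z[3] * e1[1] - z[1] * e1[3],
            z[1] * e1[2] - z[2] * e1[1])
    cb <- stats::runif(n_frames, cos(th), 1)
    sb <- sqrt(1 - cb^2)
    ph <- stats::runif(n_frames, 0, 2 * pi)
    U[i, , ] <- t(outer(sb * cos(ph), e1) + outer(sb * sin(ph), e2) +
                    outer(cb, z))
  }
  U
}

fibonacci_axes <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(1 - z^2)
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# Donor/acceptor fixture: a uridine N3-H3 donor pointing along +x and an
# acceptor oxygen placed at distance d (from the donor) and donor-H-acceptor
# angle ang (law of cosines, closed form).
donor_acceptor_frame <- function(d, ang) {
  n3 <- c(0, 0, 0)
  h3 <- c(1.01, 0, 0)
  h <- 1.01
  b <- -2 * h * cos(ang * pi / 180)
  x <- -b / 2 + sqrt((b / 2)^2 - (h^2 - d^2))
  acc <- h3 + x * c(cos((180 - ang) * pi / 180),
                    sin((180 - ang) * pi / 180), 0)
  make_frame(c("N3", "H3", "O"), c("N", "H", "O"),
             c(1L, 1L, 2L), c("U", "U", "HOH"),
             c("base", "base", "water"),
             rbind(n3, h3, acc))
}
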