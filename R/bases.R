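# Idealized planar nucleobase geometries, expressed in the standard base
# reference frame: the frame origin sits at the centre of an ideal
# Watson-Crick pair, x points into the major groove, y runs along the long
# axis towards the strand-1 base, and the pairing partner is obtained by
# rotating the partner's template 180 degrees about x.  In this frame C1' of
# every base lies at (-2.479, 5.346, 0), which fixes the paired C1'-C1'
# separation at 10.69 A, and the glycosidic bond makes a fixed angle lambda
# with the C1'-C1' vector.
#
# Ring geometries are constructed from idealized bond lengths and angles
# (survey means rounded to ~0.01 A / 1 deg); exocyclic substituents and
# hydrogens are placed on external bisectors.  Pseudouridine reuses the
# uracil ring, attaches the sugar through C5 and carries the extra imino
# proton HN1 on N1 (and no H5).

C1P_STANDARD <- c(-2.479, 5.346, 0)
GLYCO_LAMBDA <- 54.5    # deg between the glycosidic bond and the C1'-C1' line

# Small in-plane rotation of each base about its C1' anchor, calibrated once
# (least squares) so that the template pair geometries give Watson-Crick
# donor-acceptor distances of 2.84-2.94 A; compensates the idealized
# ring internal coordinates.
WC_EDGE_CALIBRATION <- c(A = -3.690, U = -1.195, G = -4.772,
                         C = 0.015, PSU = -0.997)

rot2 <- function(theta) {
  th <- deg2rad(theta)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Walk a planar ring from bond lengths and interior angles; closure is
# approximate and the small residual is left in the last bond.
ring_2d <- function(bonds, interior) {
  n <- length(bonds)
  pos <- matrix(0, n, 2)
  dir <- c(1, 0)
  pos[2, ] <- pos[1, ] + bonds[1] * dir
  for (k in 3:n) {
    dir <- rot2(180 - interior[k - 1]) %*% dir
    pos[k, ] <- pos[k - 1, ] + bonds[k - 1] * dir
  }
  pos
}

bisector_place_2d <- function(R, A, B, bond) {
  u <- unitv(A - R) + unitv(B - R)
  R - bond * unitv(u)
}

# Intersection of two circles in 2D, picking the solution farther from `away`.
circle_intersect_2d <- function(c1, r1, c2, r2, away) {
  d <- vnorm(c2 - c1)
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  if (h2 < 0) stop("rings do not close")
  h <- sqrt(h2)
  e <- unitv(c2 - c1)
  p <- c1 + a * e
  n <- c(-e[2], e[1])
  cand <- rbind(p + h * n, p - h * n)
  cand[which.max(c(vnorm(cand[1, ] - away), vnorm(cand[2, ] - away))), ]
}

# Build the 2D heavy-atom + hydrogen geometry of one base.  Returns a list
# with coords (named matrix), the glycosidic atom name, the chi reference
# atom, the ring atom names used for frame fitting, and the WC-edge atom.
base_2d <- function(code) {
  H_CC <- 1.08; H_NN <- 1.01
  if (code %in% c("U", "PSU", "C")) {
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    if (code == "C") {
      bonds <- c(1.397, 1.353, 1.335, 1.425, 1.339, 1.367)
      interior <- c(120.3, 119.2, 119.9, 121.9, 117.4, 121.0)
    } else {
      bonds <- c(1.381, 1.373, 1.380, 1.431, 1.337, 1.375)
      interior <- c(121.0, 114.9, 127.0, 114.6, 119.7, 122.7)
    }
    xy <- ring_2d(bonds, interior)
    rownames(xy) <- nm
    g <- function(a) xy[a, ]
    ext <- list()
    ext$O2 <- bisector_place_2d(g("C2"), g("N1"), g("N3"),
                                if (code == "C") 1.240 else 1.219)
    if (code == "C") {
      ext$N4 <- bisector_place_2d(g("C4"), g("N3"), g("C5"), 1.335)
      u <- unitv(ext$N4 - g("C4"))
      ext$H41 <- ext$N4 + H_NN * c(rot2(60) %*% u)
      ext$H42 <- ext$N4 + H_NN * c(rot2(-60) %*% u)
      ext$H5 <- bisector_place_2d(g("C5"), g("C4"), g("C6"), H_CC)
    } else {
      ext$O4 <- bisector_place_2d(g("C4"), g("N3"), g("C5"), 1.232)
      ext$H3 <- bisector_place_2d(g("N3"), g("C2"), g("C4"), H_NN)
      if (code == "U")
        ext$H5 <- bisector_place_2d(g("C5"), g("C4"), g("C6"), H_CC)
      else  # PSU: imino proton on N1; C5 is the glycosidic carbon
        ext$HN1 <- bisector_place_2d(g("N1"), g("C2"), g("C6"), H_NN)
    }
    ext$H6 <- bisector_place_2d(g("C6"), g("C5"), g("N1"), H_CC)
    coords <- rbind(xy, do.call(rbind, ext))
    glyco <- if (code == "PSU") "C5" else "N1"
    chi_ref <- if (code == "PSU") "C4" else "C2"
    glyco_bond <- if (code == "PSU") 1.50 else 1.471
    ring <- nm
    wc <- "N3"
  } else {
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    if (code == "A") {
      bonds <- c(1.339, 1.331, 1.344, 1.383, 1.406, 1.351)
      interior <- c(118.6, 129.3, 110.6, 126.8, 117.0, 117.7)
      imid <- c(N9C4 = 1.374, C8N9 = 1.371, N7C8 = 1.311, C5N7 = 1.388,
                aN9 = 105.8, aN7 = 110.7)
    } else {
      bonds <- c(1.373, 1.323, 1.350, 1.379, 1.419, 1.391)
      interior <- c(125.1, 123.9, 111.9, 128.6, 118.8, 111.5)
      imid <- c(N9C4 = 1.375, C8N9 = 1.374, N7C8 = 1.305, C5N7 = 1.388,
                aN9 = 105.4, aN7 = 110.8)
    }
    xy <- ring_2d(bonds, interior)
    rownames(xy) <- nm
    g <- function(a) xy[a, ]
    centroid <- colMeans(xy)
    side_place <- function(at, nb, angle, bond) {
      u <- unitv(g(nb) - g(at))
      cand <- rbind(g(at) + bond * c(rot2(angle) %*% u),
                    g(at) + bond * c(rot2(-angle) %*% u))
      cand[which.max(c(vnorm(cand[1, ] - centroid),
                       vnorm(cand[2, ] - centroid))), ]
    }
    N9 <- side_place("C4", "C5", imid["aN9"], imid["N9C4"])
    N7 <- side_place("C5", "C4", imid["aN7"], imid["C5N7"])
    C8 <- circle_intersect_2d(N9, imid["C8N9"], N7, imid["N7C8"], centroid)
    ext <- list(N9 = N9, N7 = N7, C8 = C8)
    ext$H8 <- bisector_place_2d(C8, N7, N9, H_CC)
    if (code == "A") {
      ext$N6 <- bisector_place_2d(g("C6"), g("N1"), g("C5"), 1.335)
      u <- unitv(ext$N6 - g("C6"))
      ext$H61 <- ext$N6 + H_NN * c(rot2(60) %*% u)
      ext$H62 <- ext$N6 + H_NN * c(rot2(-60) %*% u)
      ext$H2 <- bisector_place_2d(g("C2"), g("N1"), g("N3"), H_CC)
    } else {
      ext$O6 <- bisector_place_2d(g("C6"), g("N1"), g("C5"), 1.237)
      ext$N2 <- bisector_place_2d(g("C2"), g("N1"), g("N3"), 1.341)
      u <- unitv(ext$N2 - g("C2"))
      ext$H21 <- ext$N2 + H_NN * c(rot2(60) %*% u)
      ext$H22 <- ext$N2 + H_NN * c(rot2(-60) %*% u)
      ext$H1 <- bisector_place_2d(g("N1"), g("C2"), g("C6"), H_NN)
    }
    coords <- rbind(xy, do.call(rbind, ext))
    glyco <- "N9"
    chi_ref <- "C4"
    glyco_bond <- 1.46
    ring <- c(nm, "N9", "C8", "N7")
    wc <- "N1"
  }
  list(coords = coords, glyco = glyco, chi_ref = chi_ref,
       glyco_bond = glyco_bond, ring = ring, wc = wc)
}

#' Standard-frame template of one nucleobase
#'
#' Returns the idealized, planar base geometry positioned in the standard
#' base reference frame (see the package vignette for the conventions), with
#' all base hydrogens present.  The glycosidic C1' anchor is returned as an
#' attribute, not as an atom of the base.
#'
#' @param code one of \code{"A"}, \code{"U"}, \code{"G"}, \code{"C"},
#'   \code{"PSU"}.
#' @return a list with \code{coords} (named n x 3 matrix, z = 0),
#'   \code{glyco} (glycosidic atom name), \code{chi_ref} (the base atom that
#'   defines the glycosidic torsion), \code{ring} (atom names used for frame
#'   fitting), \code{wc} (the central Watson-Crick edge atom) and
#'   \code{c1p} (the C1' anchor position).
#' @export
base_template <- function(code) {
  b <- base_2d(code)
  xy <- b$coords
  gl <- xy[b$glyco, ]
  nbrs <- ring_neighbours(b$glyco)
  c1p <- bisector_place_2d(gl, xy[nbrs[1], ], xy[nbrs[2], ], b$glyco_bond)
  # rigid 2D map: C1' -> standard anchor, glycosidic direction -> lambda
  u_target <- c(sin(deg2rad(GLYCO_LAMBDA)), -cos(deg2rad(GLYCO_LAMBDA)))
  u_src <- unitv(gl - c1p)
  co <- sum(u_src * u_target); si <- u_src[1] * u_target[2] - u_src[2] * u_target[1]
  R <- matrix(c(co, si, -si, co), 2, 2)
  place <- function(refl) {
    xy2 <- xy
    if (refl) {
      # reflect across the glycosidic line before rotating
      ax <- u_src
      for (k in seq_len(nrow(xy2))) {
        v <- xy2[k, ] - c1p
        xy2[k, ] <- c1p + 2 * sum(v * ax) * ax - v
      }
    }
    sweep(t(R %*% t(sweep(xy2, 2, c1p))), 2, C1P_STANDARD[1:2], "+")
  }
  cand <- list(place(FALSE), place(TRUE))
  # correct mirror image: the WC edge atom must face the pair centre
  pick <- which.min(vapply(cand, function(m) vnorm(m[b$wc, ]), 0))
  xy_std <- cand[[pick]]
  delta <- WC_EDGE_CALIBRATION[[code]]
  Rc <- rot2(delta)
  xy_std <- sweep(t(Rc %*% t(sweep(xy_std, 2, C1P_STANDARD[1:2]))),
                  2, C1P_STANDARD[1:2], "+")
  coords <- cbind(xy_std, 0)
  colnames(coords) <- c("x", "y", "z")
  list(coords = coords, glyco = b$glyco, chi_ref = b$chi_ref,
       ring = b$ring, wc = b$wc,
       c1p = C1P_STANDARD)
}

ring_neighbours <- function(atom) {
  switch(atom,
         N1 = c("C2", "C6"),
         N9 = c("C4", "C8"),
         C5 = c("C4", "C6"),
         stop("no glycosidic neighbours defined for ", atom))
}

# memoized templates
.template_cache <- new.env(parent = emptyenv())
get_template <- function(code) {
  if (is.null(.template_cache[[code]]))
    .template_cache[[code]] <- base_template(code)
  .template_cache[[code]]
}
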