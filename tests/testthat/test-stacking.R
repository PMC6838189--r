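test_that("Coulomb and Lennard-Jones closed forms are exact", {
  ffq <- point_forcefield(charge = 0.5, sigma = 0, epsilon = 0)
  f1 <- point_fragment(c(0, 0, 0))
  f2 <- point_fragment(c(3, 0, 0))
  e <- pair_energy(f1, f2, ffq)
  expect_equal(unname(e["elec"]), 332.0637 * 0.25 / 3, tolerance = 1e-12)
  expect_equal(unname(e["vdw"]), 0)
  # one LJ pair at its minimum distance gives exactly -epsilon
  fflj <- point_forcefield(charge = 0, sigma = 3.4, epsilon = 0.12)
  r_min <- 2^(1 / 6) * 3.4
  e2 <- pair_energy(point_fragment(c(0, 0, 0)),
                    point_fragment(c(r_min, 0, 0)), fflj)
  expect_equal(unname(e2["total"]), -0.12, tolerance = 1e-12)
})

test_that("pair energies equal the naive double-loop oracle", {
  set.seed(81)
  ff <- default_forcefield()
  for (k in 1:8) {
    f1 <- random_fragment(12, centre = c(0, 0, 0), code = "U")
    f2 <- random_fragment(12, centre = c(8, 0, 0), code = "A")
    got <- pair_energy(f1, f2, ff)
    want <- pair_energy_oracle(f1, f2, ff)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("pair energy is symmetric and invariant under rigid motion", {
  set.seed(82)
  ff <- default_forcefield()
  f1 <- random_fragment(10, c(0, 0, 0), "G")
  f2 <- random_fragment(10, c(9, 0, 0), "C")
  expect_equal(pair_energy(f1, f2, ff), pair_energy(f2, f1, ff),
               tolerance = 1e-12)
  R <- psihelix:::rot_about_axis(c(1, 1, 0), 33)
  move <- function(f) {
    f$xyz <- sweep(f$xyz %*% t(R), 2, c(5, -2, 1), "+")
    f
  }
  expect_equal(pair_energy(move(f1), move(f2), ff),
               pair_energy(f1, f2, ff), tolerance = 1e-9)
})

test_that("clashing or unparameterized atoms are rejected", {
  ff <- default_forcefield()
  f1 <- list(code = "U", names = "O2", xyz = rbind(c(0, 0, 0)))
  f2 <- list(code = "U", names = "O4", xyz = rbind(c(0.3, 0, 0)))
  expect_error(pair_energy(f1, f2, ff), "0.5 A")
  f3 <- list(code = "U", names = "QQ", xyz = rbind(c(3, 0, 0)))
  expect_error(pair_energy(f1, f3, ff), "unparameterized")
})

test_that("the step decomposition identity holds to machine precision", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  ff <- default_forcefield()
  for (i in c(1, 4, 5, 8)) {
    e <- step_stacking_energy(fr, topo, i, ff)
    resid <- e$dE_step - (e$E_AB + e$E_CD + e$E_AC + e$E_BD)
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("energies vanish for well-separated bases and decay monotonically", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  ff <- default_forcefield()
  f1 <- base_fragment(fr, 4)
  f2 <- base_fragment(fr, 5)
  far <- f2; far$xyz <- sweep(far$xyz, 2, c(50, 0, 0), "+")
  # base fragments carry a small net monopole, so the floor at 50 A is the
  # monopole-monopole term k q1 q2 / r, about 0.1 kcal/mol here
  expect_lt(abs(pair_energy(f1, far, ff)["total"]), 0.2)
  shifts <- c(20, 40, 80, 160)
  mags <- vapply(shifts, function(s) {
    fs <- f2; fs$xyz <- sweep(fs$xyz, 2, c(s, 0, 0), "+")
    abs(pair_energy(f1, fs, ff)["total"])
  }, 0)
  expect_true(all(diff(mags) < 0))
})

test_that("exactly 8 unique steps and 16 motifs are enumerated, matching brute force", {
  steps <- enumerate_unique_steps()
  expect_equal(nrow(steps), 8)
  expect_false(anyDuplicated(steps$label) > 0)
  motifs <- enumerate_trinucleotide_motifs()
  expect_length(motifs, 16)
  expect_false(anyDuplicated(motifs) > 0)
  # brute force: all (side, neighbour) placements, normalized so the
  # pseudouridine sits on strand 1, reduced under strand exchange
  wc <- c(A = "U", U = "A", G = "C", C = "G", P = "A")
  canon <- character()
  for (x in c("A", "C", "G", "U")) {
    for (side in c("5prime", "3prime")) {
      s1 <- if (side == "5prime") c(x, "P") else c("P", x)
      s2 <- unname(wc[s1])
      lab1 <- paste0(paste(s1, collapse = ""), "/", paste(s2, collapse = ""))
      # strand exchange: read the complementary strand 5'->3'
      s1x <- rev(s2); s2x <- rev(s1)
      lab2 <- paste0(paste(s1x, collapse = ""), "/", paste(s2x, collapse = ""))
      canon <- c(canon, min(lab1, lab2))
    }
  }
  expect_length(unique(canon), 8)
  # each enumerated label or its strand-exchange image appears in brute force
  for (lab in steps$label) {
    p <- strsplit(lab, "/")[[1]]
    s1 <- strsplit(p[1], "")[[1]]; s2 <- strsplit(p[2], "")[[1]]
    alt <- paste0(paste(rev(s2), collapse = ""), "/",
                  paste(rev(s1), collapse = ""))
    expect_true(min(lab, alt) %in% canon)
  }
})

test_that("trinucleotide predictions are additive, linear and label-consistent", {
  steps <- enumerate_unique_steps()
  zero <- data.frame(label = steps$label, ddE = 0)
  expect_true(all(trinucleotide_prediction(zero)$ddE == 0))
  set.seed(83)
  tab <- data.frame(label = steps$label, ddE = rnorm(8))
  pred <- trinucleotide_prediction(tab)
  expect_equal(nrow(pred), 16)
  # GPG = (GP/CA) + (PG/AC) by label algebra
  gpg <- pred$ddE[pred$motif == "GPG"]
  expect_equal(gpg, tab$ddE[tab$label == "GP/CA"] +
                 tab$ddE[tab$label == "PG/AC"])
  # linearity under scaling
  tab3 <- tab; tab3$ddE <- 3 * tab3$ddE
  pred3 <- trinucleotide_prediction(tab3)
  expect_equal(pred3$ddE[match(pred$motif, pred3$motif)], 3 * pred$ddE)
  # sorted by increasing ddE
  expect_true(all(diff(pred$ddE) >= 0))
  expect_error(trinucleotide_prediction(tab[-3, ]), "missing")
})

test_that("modification deltas subtract homologous steps only", {
  topo_m <- duplex_preset("CPG")
  topo_r <- duplex_preset("CUG")
  fm <- build_aform_duplex(topo_m)
  fr <- build_aform_duplex(topo_r)
  ff <- default_forcefield()
  dm <- step_stacking_energy(fm, topo_m, 5, ff)
  dr <- step_stacking_energy(fr, topo_r, 5, ff)
  md <- modification_delta(dm, dr)
  expect_equal(md$label, "PG/AC")
  expect_equal(unname(md$ddE["total"]),
               unname(dm$dE_step["total"] - dr$dE_step["total"]))
  # identical inputs give zero
  md0 <- modification_delta(dr, dr)  # U vs U: labels already match
  expect_equal(unname(md0$ddE["total"]), 0)
  # the reported headline arithmetic
  expect_equal(-10.0 - (-8.41), -1.59)
  dr4 <- step_stacking_energy(fr, topo_r, 4, ff)
  expect_error(modification_delta(dm, dr4), "not homologous")
})

test_that("imported external energies drive the same downstream machinery", {
  steps <- enumerate_unique_steps()
  set.seed(84)
  tab <- data.frame(label = steps$label,
                    e_modif = rnorm(8, -10), e_unmodif = rnorm(8, -9))
  dd <- import_qm_energies(tab)
  expect_equal(attr(dd, "source"), "QM imported")
  pred <- trinucleotide_prediction(dd)
  expect_equal(nrow(pred), 16)
  expect_equal(ddE_rank_correlation(dd, dd), 1)
  tab2 <- rbind(tab, tab[1, ])
  expect_error(import_qm_energies(tab2), "duplicate")
  tab3 <- tab; tab3$label[1] <- "ZZ/XX"
  expect_error(import_qm_energies(tab3), "unknown")
})

test_that("tetramer preparation is exact on-template and equivariant", {
  topo <- duplex_preset("GPC")
  fr <- build_aform_duplex(topo)
  pt <- prepare_tetramer_geometry(fr, topo, 4)
  expect_true(all(pt$fit_rmsd < 1e-6))
  expect_length(pt$flags, 0)
  # rigid rotation of the scaffold rotates the output identically
  R <- psihelix:::rot_about_axis(c(0, 1, 2), 28)
  t0 <- c(3, 3, 3)
  moved <- set_frame_coords(fr, sweep(frame_coords(fr) %*% t(R), 2, t0, "+"))
  pt2 <- prepare_tetramer_geometry(moved, topo, 4)
  for (nm in c("A", "B", "C", "D")) {
    want <- sweep(pt$fragments[[nm]] %*% t(R), 2, t0, "+")
    expect_lt(max(abs(pt2$fragments[[nm]] - want)), 1e-6)
  }
})

test_that("tetramer fit residual matches the Gaussian closed form", {
  topo <- duplex_preset("GPC")
  fr <- build_aform_duplex(topo)
  sigma <- 0.1
  set.seed(85)
  rms <- replicate(40, {
    xyz <- frame_coords(fr)
    noisy <- set_frame_coords(fr, xyz + matrix(rnorm(length(xyz), sd = sigma),
                                               nrow(xyz), 3))
    mean(suppressWarnings(prepare_tetramer_geometry(noisy, topo, 4))$fit_rmsd)
  })
  # fitting removes 6 of the 3n degrees of freedom per base (n = 6 or 9)
  expected <- mean(vapply(c(9, 6, 6, 9), function(n)
    sigma * sqrt(3 * (1 - 2 / n)), 0))
  expect_lt(abs(mean(rms) - expected), 0.1 * expected)
})
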