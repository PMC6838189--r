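test_that("dihedral follows the IUPAC convention on planar quartets", {
  p1 <- c(1, 1, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  expect_equal(dihedral(p1, p2, p3, c(1, 0, 0)), 0)          # cis
  expect_equal(dihedral(p1, p2, p3, c(-1, 0, 0)), 180)       # trans
  t1 <- dihedral(p1, p2, p3, c(0.5, 0, 0.5))
  mirror <- function(p) c(p[1], p[2], -p[3])
  t2 <- dihedral(mirror(p1), mirror(p2), mirror(p3),
                 mirror(c(0.5, 0, 0.5)))
  expect_equal(t2, -t1)
  expect_error(dihedral(p1, p1, p3, c(1, 0, 0)), "coincident")
})

test_that("glycosidic chi uses the C-glycoside definition for pseudouridine", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  chi_direct <- psihelix:::wrap360(frame_torsion(fr, list(
    c(5, "O4'"), c(5, "C1'"), c(5, "C5"), c(5, "C4"))))
  expect_equal(glycosidic_chi(fr, 5), chi_direct)
  chi_a <- psihelix:::wrap360(frame_torsion(fr, list(
    c(14, "O4'"), c(14, "C1'"), c(14, "N9"), c(14, "C4"))))
  expect_equal(glycosidic_chi(fr, 14), chi_a)
  expect_true(all(vapply(1:18, function(r) {
    v <- glycosidic_chi(fr, r); v >= 0 && v < 360
  }, logical(1))))
})

test_that("pseudorotation agrees with an independent least-squares fit", {
  set.seed(41)
  ring_frame <- function(P, taum) {
    # extreme random pucker states may leave a slightly larger closure
    # residual; that is immaterial to the phase/amplitude comparison
    m <- suppressWarnings(psihelix:::ribose_ring(P, taum))
    make_frame(rownames(m), c("C", "C", "C", "C", "O"), 1L, "U", "sugar", m)
  }
  cases <- data.frame(P = runif(25, 0, 360), taum = runif(25, 35, 45))
  for (k in seq_len(nrow(cases))) {
    fr <- ring_frame(cases$P[k], cases$taum[k])
    pk <- pseudorotation(fr, 1)
    oracle <- pucker_fit_oracle(pk$nu)
    dp <- abs(((pk$phase - oracle$phase + 180) %% 360) - 180)
    expect_lt(dp, 2)
    expect_equal(pk$amplitude, oracle$amplitude, tolerance = 0.05)
    # and the generator reproduces its target state
    dpt <- abs(((pk$phase - cases$P[k] + 180) %% 360) - 180)
    expect_lt(dpt, 1.5)
  }
})

test_that("mirroring a sugar advances the pseudorotation phase by 180", {
  m <- psihelix:::ribose_ring(11, 42)
  fr <- make_frame(rownames(m), c("C", "C", "C", "C", "O"), 1L, "U",
                   "sugar", m)
  mm <- m; mm[, 3] <- -mm[, 3]
  frm <- make_frame(rownames(mm), c("C", "C", "C", "C", "O"), 1L, "U",
                    "sugar", mm)
  p1 <- pseudorotation(fr, 1)$phase
  p2 <- pseudorotation(frm, 1)$phase
  expect_equal((p2 - p1) %% 360, 180, tolerance = 0.5)
})

test_that("C3'-endo and C3'-exo land in their pseudorotation quadrants", {
  for (P in c(5, 18, 35)) {
    m <- psihelix:::ribose_ring(P, 40)
    fr <- make_frame(rownames(m), c("C", "C", "C", "C", "O"), 1L, "U",
                     "sugar", m)
    expect_lt(pseudorotation(fr, 1)$phase, 36)
  }
  m <- psihelix:::ribose_ring(190, 40)
  fr <- make_frame(rownames(m), c("C", "C", "C", "C", "O"), 1L, "U",
                   "sugar", m)
  expect_gt(pseudorotation(fr, 1)$phase, 180)
})

test_that("distance series report exact separations with summaries", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  fr <- make_frame(c("P", "P"), c("P", "P"), c(1L, 2L), c("U", "U"),
                   "backbone", xyz)
  tr <- trajectory(list(fr, fr))
  ds <- distance_series(tr, c(1, "P"), c(2, "P"))
  expect_equal(ds$distances, c(5, 5))
  expect_equal(ds$mean, 5)
  expect_equal(ds$sd, 0)
  expect_error(distance_series(tr, c(1, "P"), c(3, "P")), "not found")
})
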