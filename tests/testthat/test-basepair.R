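test_that("an ideal pair in its reference arrangement has zero parameters", {
  topo <- duplex_preset("GPC")
  fr <- build_aform_duplex(topo)
  for (i in c(1, 5, 9)) {
    bp <- base_pair_params(fr, topo, i)
    expect_equal(bp$opening, 0, tolerance = 0.1)
    expect_equal(bp$buckle, 0, tolerance = 0.1)
    expect_equal(bp$propeller, 0, tolerance = 0.1)
    expect_equal(bp$shear, 0, tolerance = 0.02)
    expect_equal(bp$stretch, 0, tolerance = 0.02)
    expect_equal(bp$stagger, 0, tolerance = 0.02)
    expect_equal(bp$c1c1, 10.692, tolerance = 0.01)
  }
})

test_that("step and helical parameters recover the construction values", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  for (i in c(2, 5, 7)) {
    sp <- step_params(fr, topo, i)
    expect_equal(sp$twist, 32.7, tolerance = 0.05)
    expect_equal(sp$rise, 2.81, tolerance = 0.02)
    expect_equal(sp$tilt, 0, tolerance = 0.1)
    expect_equal(sp$roll, 0, tolerance = 0.1)
  }
  hp <- helical_parameters(fr, topo)
  expect_equal(hp$twist, 32.7, tolerance = 0.05)
  expect_equal(hp$rise, 2.81, tolerance = 0.01)
})

test_that("pair and step parameters are invariant under rigid motion", {
  topo <- duplex_preset("APU")
  fr <- build_aform_duplex(topo)
  R <- psihelix:::rot_about_axis(c(2, -1, 4), 71)
  moved <- set_frame_coords(fr, sweep(frame_coords(fr) %*% t(R), 2,
                                      c(10, -5, 3), "+"))
  b1 <- base_pair_params(fr, topo, 5)
  b2 <- base_pair_params(moved, topo, 5)
  for (f in c("shear", "stretch", "stagger", "buckle", "propeller",
              "opening")) {
    expect_equal(b2[[f]], b1[[f]], tolerance = 1e-6)
  }
  s1 <- step_params(fr, topo, 4)
  s2 <- step_params(moved, topo, 4)
  for (f in c("shift", "slide", "rise", "tilt", "roll", "twist")) {
    expect_equal(s2[[f]], s1[[f]], tolerance = 1e-6)
  }
})

test_that("a heavily distorted base is flagged by its fit RMSD", {
  topo <- build_topology("AU", "AU")
  fr <- build_aform_duplex(topo)
  at <- fr$atoms
  idx <- which(at$residue_index == 1 & at$klass == "base")
  set.seed(7)
  xyz <- frame_coords(fr)
  xyz[idx, ] <- xyz[idx, ] + matrix(rnorm(3 * length(idx), sd = 0.8),
                                    length(idx), 3)
  fr2 <- set_frame_coords(fr, xyz)
  f <- fit_base_frame(fr2, 1)
  expect_gt(f$fit_rmsd, 0.5)
  expect_equal(f$flag, "distorted")
})
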