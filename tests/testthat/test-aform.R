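test_that("the generated duplex has Watson-Crick geometry at the Psi-A pair", {
  topo <- duplex_preset("GPC")
  fr <- build_aform_duplex(topo)
  expect_equal(nrow(unique(fr$atoms["residue_index"])), 18)
  hb <- detect_hbonds(fr)
  at <- fr$atoms
  # N3-H3(Psi5) ... N1(A14)
  i_n3 <- atom_index(fr, 5, "N3"); i_n1 <- atom_index(fr, 14, "N1")
  expect_true(any(hb$donor == i_n3 & hb$acceptor == i_n1))
  # A14 amino donates to the Psi5 Watson-Crick carbonyl
  i_n6 <- atom_index(fr, 14, "N6")
  acc5 <- at$residue_index[hb$acceptor] == 5 &
    at$name[hb$acceptor] %in% c("O2", "O4")
  expect_true(any(hb$donor == i_n6 & acc5))
})

test_that("sugars are C3'-endo at the configured pucker and chi is anti", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  for (r in 1:18) {
    pk <- pseudorotation(fr, r)
    expect_gte(pk$phase, 0)
    expect_lt(pk$phase, 36)
    expect_equal(pk$phase, 11, tolerance = 0.2)
    expect_equal(pk$amplitude, 42, tolerance = 0.2)
    chi <- glycosidic_chi(fr, r)
    expect_true(chi > 170 && chi < 280)  # anti range
  }
  expect_equal(glycosidic_chi(fr, 5), 195, tolerance = 0.5)   # PSU
  expect_equal(glycosidic_chi(fr, 4), 205, tolerance = 0.5)   # unmodified
})

test_that("paired C1'-C1' distances sit in the A-form range near 10.75", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  cc <- c1c1_distances(fr, topo)
  expect_true(all(cc$per_pair > 10.3 & cc$per_pair < 10.9))
  # deviation from the solution-structure ensemble value 10.75
  expect_lt(abs(cc$mean - 10.75), 0.15)
})

test_that("a 2-bp duplex reproduces the configured rise between pair centres", {
  topo <- build_topology("AU", "AU")
  fr <- build_aform_duplex(topo)
  hp <- helical_parameters(fr, topo)
  expect_equal(hp$rise, 2.81, tolerance = 1e-6)
})

test_that("all sugars share one handedness (signed-volume chirality)", {
  topo <- duplex_preset("UPA")
  fr <- build_aform_duplex(topo)
  sv <- vapply(1:18, function(r) {
    code <- fr$atoms$residue_code[fr$atoms$residue_index == r][1]
    g <- if (code == "PSU") "C5" else if (code %in% c("A", "G")) "N9" else "N1"
    c1 <- atom_xyz(fr, r, "C1'")
    v1 <- atom_xyz(fr, r, g) - c1
    v2 <- atom_xyz(fr, r, "O4'") - c1
    v3 <- atom_xyz(fr, r, "C2'") - c1
    sign(sum(psihelix:::cross3(v1, v2) * v3))
  }, 0)
  expect_true(all(sv == sv[1]))
})

test_that("construction is deterministic and validates its own topology", {
  topo <- duplex_preset("APU")
  f1 <- build_aform_duplex(topo)
  f2 <- build_aform_duplex(topo)
  expect_identical(frame_coords(f1), frame_coords(f2))
  expect_false(anyNA(f1$atoms$klass))
  # 5'-terminal residues carry no phosphate
  expect_error(atom_index(f1, 1, "P"), "not found")
  expect_error(atom_index(f1, 10, "P"), "not found")
  expect_silent(atom_index(f1, 2, "P"))
})

test_that("unsupported residue codes and bad pucker phases are rejected", {
  expect_error(build_topology("AXU", "AUU"), "unknown residue")
  expect_error(aform_parameters(pucker_phase = 40), "C3'-endo")
})
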