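test_that("duplex topology builds the studied 9-mer with its Psi-A pair", {
  topo <- build_topology("UCACPGAGU", "ACUCAGUGA", mods = 5)
  expect_equal(topo$N, 9)
  expect_equal(topo$pairing[5], 14L)
  expect_equal(topo$strand1[5], "PSU")
  expect_equal(residue_code(topo, 14), "A")
  expect_equal(topo$mod_positions, 5L)
})

test_that("minimal duplexes pair antiparallel and reject mismatches", {
  topo <- build_topology("AU", "AU")
  expect_equal(topo$pairing[1], 4L)
  expect_equal(topo$pairing[2], 3L)
  expect_error(build_topology("AA", "AA"), "non-complementary")
  expect_error(build_topology("UCA", "UGC"), "position")
  expect_error(build_topology("ACG", "CGU", mods = 1), "not at a uridine")
  expect_error(build_topology("AUG", "AU"), "length")
})

test_that("pairing is an involution for every preset", {
  for (nm in names(duplex_presets())) {
    topo <- duplex_preset(nm)
    expect_equal(topo$pairing[topo$pairing], seq_len(2 * topo$N))
  }
})

test_that("atom classification is total and partitions each residue", {
  topo <- duplex_preset("GPC")
  frame <- build_aform_duplex(topo)
  at <- frame$atoms
  expect_false(anyNA(at$klass))
  for (r in unique(at$residue_index)) {
    k <- at$klass[at$residue_index == r]
    expect_true(all(k %in% c("base", "sugar", "backbone")))
  }
  # PSU base set: HN1 present, no H5
  psu <- at[at$residue_index == 5, ]
  expect_true("HN1" %in% psu$name[psu$klass == "base"])
  expect_false("H5" %in% psu$name)
  # the stated classification examples
  u1 <- at[at$residue_index == 2 & at$name == "H5", ]  # a C residue has H5
  expect_equal(unique(at$klass[at$name == "OP2"]), "backbone")
  expect_equal(unique(at$klass[at$name == "H5"]), "base")
})

test_that("classification rejects unknown atom names", {
  topo <- build_topology("AU", "AU")
  frame <- build_aform_duplex(topo)
  frame$atoms$name[3] <- "XX9"
  expect_error(classify_atoms(frame, topo), "XX9")
})

test_that("legacy atom names normalize to the modern ones", {
  expect_equal(normalize_atom_names(c("O1P", "O2P", "C1*"), c("A", "A", "A")),
               c("OP1", "OP2", "C1'"))
  expect_equal(normalize_atom_names("H1", "PSU"), "HN1")
  expect_equal(normalize_atom_names("H1", "G"), "H1")
})

test_that("force-field table loads with full coverage and flags PSU", {
  ff <- default_forcefield()
  expect_s3_class(ff, "forcefield_parameters")
  expect_equal(attr(ff, "psu_charges"), "surrogate")
  expect_equal(attr(ff, "coulomb_constant"), 332.0637)
  for (code in c("A", "U", "G", "C", "PSU")) {
    nm <- base_atom_names(code)
    expect_silent(psihelix:::ff_lookup(ff, rep(code, length(nm)), nm))
  }
  # PSU base fragment carries the same net charge as uridine's
  s_u <- sum(ff$charge[ff$residue_code == "U"])
  s_p <- sum(ff$charge[ff$residue_code == "PSU"])
  expect_equal(s_p, s_u, tolerance = 1e-6)
  expect_error(psihelix:::ff_lookup(ff, "A", "ZZ"), "unparameterized")
})
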