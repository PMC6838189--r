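test_that("the detector reproduces the stated distance/angle criteria", {
  crit <- hbond_criteria()
  don <- data.frame(donor = 1L, hydrogen = 2L)
  hit <- detect_hbonds(donor_acceptor_frame(2.9, 170), don, 3L, crit)
  expect_equal(nrow(hit), 1)
  expect_equal(nrow(detect_hbonds(donor_acceptor_frame(3.05, 170),
                                  don, 3L, crit)), 0)
  expect_equal(nrow(detect_hbonds(donor_acceptor_frame(2.9, 130),
                                  don, 3L, crit)), 0)
  # boundary: just inside both limits counts
  expect_equal(nrow(detect_hbonds(donor_acceptor_frame(3.0 - 1e-6,
                                                       135 + 1e-4),
                                  don, 3L, crit)), 1)
  expect_error(hbond_criteria(d_max = -1))
  expect_error(hbond_criteria(theta_min = 200))
})

test_that("detection equals the all-triples brute-force oracle", {
  set.seed(71)
  topo <- build_topology("AUG", "CAU")
  base <- build_aform_duplex(topo)
  for (k in 1:25) {
    fr <- solvate_random(base, 30, box = c(30, 30, 30), min_dist = 1.6,
                         seed = k)
    don <- frame_donors(fr)
    acc <- frame_acceptors(fr)
    crit <- hbond_criteria(d_max = 3.5, theta_min = 120)
    got <- detect_hbonds(fr, don, acc, crit)
    got_m <- as.matrix(got[order(got$donor, got$acceptor),
                           c("donor", "hydrogen", "acceptor")])
    oracle <- hbond_oracle(fr, don, acc, crit)
    expect_equal(unname(got_m), unname(oracle))
  }
})

test_that("bridge occupancy counts bridged frames exactly", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  wt <- place_bridge_waters(fr, "intra_bridge", 5, n_frames = 10,
                            occupancy_fraction = 0.3, seed = 5)
  bo <- bridge_occupancy(wt, c(5, "HN1"), c(5, "OP2"))
  expect_equal(bo$occupancy, 30)
  expect_equal(bo$label, "OP2(5)-W-HN1(5)")
  expect_error(bridge_occupancy(wt, c(5, "HN1"), c(5, "HN1")), "differ")
})

test_that("occupancy is frame-order invariant but lifetime is not", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  wt <- place_bridge_waters(fr, "intra_bridge", 5, n_frames = 12,
                            occupancy_fraction = 0.5, seed = 6)
  s <- bridge_series(wt, c(5, "HN1"), c(5, "OP2"))
  perm <- c(seq(2, 12, 2), seq(1, 11, 2))
  wt_p <- trajectory(wt$frames[perm], dt = wt$dt)
  s_p <- bridge_series(wt_p, c(5, "HN1"), c(5, "OP2"))
  expect_equal(mean(s_p), mean(s))
  expect_equal(s_p, s[perm])
  # a crafted series shows lifetime depends on ordering
  a <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  b <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(lifetime_from_series(a, 10), 0.03)
  expect_equal(lifetime_from_series(b, 10), 0.01)
})

test_that("lifetimes follow the run-length definition", {
  s <- rep(FALSE, 10); s[3:7] <- TRUE
  expect_equal(lifetime_from_series(s, 10), 0.05)
  alt <- rep(c(TRUE, FALSE), 5)
  expect_equal(lifetime_from_series(alt, 10), 0.01)
  two <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(lifetime_from_series(two, 10), 0.03)
  expect_equal(lifetime_from_series(rep(FALSE, 5), 10), 0)
})

test_that("single-water occupancy never exceeds the combined-path occupancy", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  wt <- place_bridge_waters(fr, "two_water_chain", 5, n_frames = 40,
                            occupancy_fraction = 0.5, seed = 7)
  s1 <- bridge_series(wt, c(5, "HN1"), c(4, "OP2"), chain_order = 1)
  s2 <- bridge_series(wt, c(5, "HN1"), c(4, "OP2"), chain_order = 2)
  expect_lte(mean(s1), mean(s1 | s2))
})

test_that("RDF of an engineered shell peaks in the right bin and integrates", {
  set.seed(72)
  n <- 400
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rad <- runif(n, 2.0, 2.1)
  olist <- lapply(seq_len(n), function(k)
    psihelix:::make_water(rad[k] * dirs[k, ], 2 * rad[k] * dirs[k, ]))
  at <- do.call(rbind, lapply(seq_along(olist), function(k)
    data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
               residue_index = k, residue_code = "HOH", klass = "water",
               x = olist[[k]][, 1], y = olist[[k]][, 2],
               z = olist[[k]][, 3])))
  fr <- conformation_frame(at)
  tr <- trajectory(list(fr))
  prof <- rdf(tr, c(0, 0, 0), bin = 0.1, r_max = 5)
  expect_equal(prof$r[which.max(prof$g)], 2.05, tolerance = 0.051)
  # exact-shell-volume normalization conserves the particle count
  shell_vol <- 4 / 3 * pi * diff(seq(0, 5, 0.1)^3)
  expect_equal(sum(prof$g * prof$density * shell_vol), n,
               tolerance = 0.02 * n)
})

test_that("occupancy grids localize static and absent waters correctly", {
  w <- psihelix:::make_water(c(1.2, 3.4, -0.7), c(2, 3.4, -0.7))
  at <- data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
                   residue_index = 1L, residue_code = "HOH", klass = "water",
                   x = w[, 1], y = w[, 2], z = w[, 3])
  fr <- conformation_frame(at)
  g <- occupancy_grid(trajectory(list(fr, fr)), spacing = 0.5)
  expect_equal(sum(g$counts == 1), 1)
  expect_equal(sum(g$counts), 1)
  expect_error(occupancy_grid(trajectory(list(fr)), spacing = 0),
               "positive")
})

test_that("the constructed half-occupied bridge shows up in the grid", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  wt <- place_bridge_waters(fr, "intra_bridge", 5, n_frames = 20,
                            occupancy_fraction = 0.5, seed = 8)
  g <- occupancy_grid(wt, spacing = 0.5)
  expect_equal(max(g$counts), 0.5)
  # the high-occupancy voxel lies between HN1 and OP2 of residue 5
  idx <- which(g$counts == max(g$counts), arr.ind = TRUE)[1, ]
  centre <- g$origin + (idx - 0.5) * g$spacing
  mid <- (atom_xyz(fr, 5, "HN1") + atom_xyz(fr, 5, "OP2")) / 2
  expect_lt(sqrt(sum((centre - mid)^2)), 3)
})

test_that("grid differences require congruent grids", {
  w <- psihelix:::make_water(c(0, 0, 0), c(1, 0, 0))
  at <- data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
                   residue_index = 1L, residue_code = "HOH", klass = "water",
                   x = w[, 1], y = w[, 2], z = w[, 3])
  fr <- conformation_frame(at)
  g1 <- occupancy_grid(trajectory(list(fr)), spacing = 0.5,
                       origin = c(-1, -1, -1), dims = c(4L, 4L, 4L))
  g2 <- occupancy_grid(trajectory(list(fr)), spacing = 0.5,
                       origin = c(-1, -1, -1), dims = c(4L, 4L, 4L))
  d <- grid_difference(g1, g2)
  expect_true(all(d$counts == 0))
  g3 <- occupancy_grid(trajectory(list(fr)), spacing = 0.25,
                       origin = c(-1, -1, -1), dims = c(4L, 4L, 4L))
  expect_error(grid_difference(g1, g3), "congruent")
})

test_that("OpenDX output has the declared item count", {
  w <- psihelix:::make_water(c(0, 0, 0), c(1, 0, 0))
  at <- data.frame(name = c("O", "H1", "H2"), element = c("O", "H", "H"),
                   residue_index = 1L, residue_code = "HOH", klass = "water",
                   x = w[, 1], y = w[, 2], z = w[, 3])
  g <- occupancy_grid(trajectory(list(conformation_frame(at))),
                      spacing = 0.5, origin = c(-1, -1, -1),
                      dims = c(3L, 3L, 3L))
  tmp <- withr::local_tempfile(fileext = ".dx")
  write_opendx(g, tmp)
  lines <- readLines(tmp)
  expect_true(any(grepl("items 27 data follows", lines)))
})
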