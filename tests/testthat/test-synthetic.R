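test_that("zero-sigma perturbation reproduces the input exactly", {
  fr <- build_aform_duplex(build_topology("AU", "AU"))
  tr <- perturb_trajectory(fr, perturbation_spec(sigma = 0, n_frames = 20,
                                                 seed = 1))
  expect_length(tr$frames, 20)
  for (k in c(1, 10, 20))
    expect_identical(frame_coords(tr$frames[[k]]), frame_coords(fr))
})

test_that("perturbation is reproducible under a seed and sensitive to it", {
  fr <- build_aform_duplex(build_topology("AU", "AU"))
  spec <- perturbation_spec(sigma = 0.2, n_frames = 5, seed = 42)
  t1 <- perturb_trajectory(fr, spec)
  t2 <- perturb_trajectory(fr, spec)
  expect_identical(frame_coords(t1$frames[[5]]), frame_coords(t2$frames[[5]]))
  t3 <- perturb_trajectory(fr, perturbation_spec(sigma = 0.2, n_frames = 5,
                                                 seed = 43))
  expect_gt(max(abs(frame_coords(t3$frames[[1]]) -
                    frame_coords(t1$frames[[1]]))), 0)
})

test_that("per-atom fluctuations converge to sigma * sqrt(3)", {
  # small toy frame so that many frames stay cheap
  xyz <- matrix(rnorm(30), 10, 3)
  fr <- make_frame(rep("C1'", 10), rep("C", 10), 1:10, rep("U", 10),
                   rep("sugar", 10), xyz)
  sigma <- 0.2
  tr <- perturb_trajectory(fr, perturbation_spec(sigma = sigma,
                                                 n_frames = 4000, seed = 9))
  X <- traj_coords(tr)
  avg <- apply(X, c(1, 2), mean)
  rmsf <- sqrt(mean(apply((X - as.vector(avg))^2, 3, mean) * 3))
  expect_lt(abs(rmsf - sigma * sqrt(3)), 0.05 * sigma * sqrt(3))
})

test_that("invalid perturbation specs are rejected", {
  expect_error(perturbation_spec(n_frames = 0), "at least 1")
  expect_error(perturbation_spec(sigma = -0.1), "non-negative")
  expect_warning(perturbation_spec(sigma = 0.5), "bond-length")
})

test_that("bridge construction errors and warnings fire as specified", {
  topo <- duplex_preset("CPG")
  fr <- build_aform_duplex(topo)
  expect_error(place_bridge_waters(fr, "intra_bridge", 5,
                                   occupancy_fraction = 1.2), "\\[0, 1\\]")
  expect_error(place_bridge_waters(fr, "intra_bridge", 4), "PSU")
  # in a regular helix HN1-OP2(5') exceeds 5.4 A: single bridge is strained
  expect_warning(place_bridge_waters(fr, "single_inter_bridge", 5,
                                     n_frames = 2), "5.4")
})

test_that("the uridine control cannot form the imino bridge", {
  topo <- duplex_preset("CUG")
  fr <- build_aform_duplex(topo)
  wt <- place_bridge_waters(fr, "intra_bridge", 5, n_frames = 10,
                            occupancy_fraction = 1, seed = 3)
  # H5 is a carbon-bound hydrogen, not a donor: no bridge is detectable
  s <- bridge_series(wt, c(5, "H5"), c(5, "OP2"))
  expect_equal(mean(s), 0)
})

test_that("bulk solvation places the exact count outside the exclusion shell", {
  topo <- build_topology("AU", "AU")
  fr <- build_aform_duplex(topo)
  sv <- solvate_random(fr, 300, box = c(35, 35, 35), min_dist = 2.5,
                       seed = 10)
  at <- sv$atoms
  expect_equal(sum(at$klass == "water" & at$name == "O"), 300)
  wo <- frame_coords(sv, at$klass == "water" & at$name == "O")
  solute <- frame_coords(sv, !(at$klass %in% "water"))
  dmin <- min(vapply(seq_len(nrow(wo)), function(k)
    min(sqrt(rowSums(sweep(solute, 2, wo[k, ])^2))), 0))
  expect_gte(dmin, 2.5)
  expect_equal(sv$box, c(35, 35, 35))
  # reproducibility and the empty case
  sv2 <- solvate_random(fr, 300, box = c(35, 35, 35), min_dist = 2.5,
                        seed = 10)
  expect_identical(frame_coords(sv), frame_coords(sv2))
  expect_identical(solvate_random(fr, 0, box = c(35, 35, 35)), fr)
  expect_error(solvate_random(fr, 10, box = c(35, 35, 35), min_dist = 1),
               "1.5")
})

test_that("an impossible solvation request fails after bounded retries", {
  topo <- build_topology("AU", "AU")
  fr <- build_aform_duplex(topo)
  # box fully inside the exclusion zone of the solute
  expect_error(solvate_random(fr, 5, box = c(2, 2, 2), min_dist = 20,
                              seed = 1), "bounded retries")
})
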