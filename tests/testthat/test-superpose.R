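test_that("superposition of identical and rigidly moved coordinates is exact", {
  set.seed(31)
  X <- matrix(rnorm(30), 10, 3)
  sp <- superpose(X, X)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  R <- psihelix:::rot_about_axis(c(1, 2, 3), 37)
  Y <- sweep(X %*% t(R), 2, c(4, -2, 7), "+")
  sp2 <- superpose(X, Y)
  expect_lt(sp2$rmsd, 1e-6)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch agrees with the quaternion-method oracle", {
  set.seed(32)
  for (k in 1:10) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
    expect_equal(superpose(X, Y)$rmsd, quaternion_superpose(X, Y)$rmsd,
                 tolerance = 1e-8)
  }
})

test_that("degenerate selections are rejected", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line + 1), "degenerate")
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
})

test_that("RMSD is invariant under a common rigid transform", {
  set.seed(33)
  X <- matrix(rnorm(45), 15, 3)
  Y <- X + matrix(rnorm(45, sd = 0.3), 15, 3)
  r0 <- superpose(X, Y)$rmsd
  R <- psihelix:::rot_about_axis(c(0, 1, 1), 63)
  move <- function(m) sweep(m %*% t(R), 2, c(-3, 5, 2), "+")
  expect_equal(superpose(move(X), move(Y))$rmsd, r0, tolerance = 1e-9)
})

test_that("Gaussian-noise RMSD matches the sigma*sqrt(3) closed form", {
  topo <- build_topology("AUGC", "GCAU")
  fr <- build_aform_duplex(topo)
  sigma <- 0.2
  tr <- perturb_trajectory(fr, perturbation_spec(sigma = sigma,
                                                 n_frames = 400, seed = 5))
  m <- mean(rmsd_series(tr, fr))
  expect_lt(abs(m - sigma * sqrt(3)), 0.05 * sigma * sqrt(3))
  # static trajectory gives zero
  tr0 <- perturb_trajectory(fr, perturbation_spec(sigma = 0, n_frames = 5,
                                                  seed = 1))
  expect_equal(max(rmsd_series(tr0, fr)), 0, tolerance = 1e-12)
  expect_error(rmsd_series(tr, fr, sel = integer()), "empty selection")
})

test_that("per-residue backbone RMSF matches the closed form and flags 5' ends", {
  topo <- build_topology("AUGC", "GCAU")
  fr <- build_aform_duplex(topo)
  sigma <- 0.2
  tr <- perturb_trajectory(fr, perturbation_spec(sigma = sigma,
                                                 n_frames = 600, seed = 6))
  rf <- rmsf_per_residue(tr)
  expect_lt(abs(mean(rf$rmsf) - sigma * sqrt(3)), 0.05 * sigma * sqrt(3))
  expect_equal(rf$flag[rf$residue_index == 1], "partial")
  expect_equal(rf$flag[rf$residue_index == 2], "")
  # static trajectory: all fluctuations vanish
  tr0 <- perturb_trajectory(fr, perturbation_spec(sigma = 0, n_frames = 4,
                                                  seed = 2))
  expect_equal(max(rmsf_per_residue(tr0)$rmsf), 0, tolerance = 1e-10)
})

test_that("ensemble maximum RMSD to the average is zero for identical models", {
  fr <- build_aform_duplex(build_topology("AU", "AU"))
  tr <- trajectory(list(fr, fr, fr))
  expect_equal(ensemble_max_rmsd(tr)$max_rmsd, 0, tolerance = 1e-10)
})
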