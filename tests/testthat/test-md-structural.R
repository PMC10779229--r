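# Trajectory analytics: selections, distances, distributions, densities,
# Coulomb energetics, superposition and clustering.

test_that("equilibration discard drops the leading frame fraction", {
  tr <- two_group_traj(n_frames = 14)
  kept <- discard_equilibration(tr, 1 / 7)
  expect_length(kept$coords, 12)
  expect_identical(kept$coords[[1]], tr$coords[[3]])
  expect_length(discard_equilibration(tr, 0)$coords, 14)
  expect_error(discard_equilibration(tr, 1), "fraction")
})

test_that("selection language filters by residue, name and chain", {
  tr <- two_group_traj()
  expect_length(select_atoms(tr, "resid 1"), 3)
  expect_length(select_atoms(tr, "resid 1 and name OD1 OD2 CG"), 3)
  expect_length(select_atoms(tr, "name NH1 NH2"), 2)
  expect_length(select_atoms(tr, "chain A"), 7)
  expect_error(select_atoms(tr, "resid 99"), "no atoms")
  expect_error(select_atoms(tr, "foo 1"), "keyword")
})

test_that("group distances use the center of mass", {
  # single atoms at (0,0,0) and (3,4,0): classic 3-4-5
  atoms <- data.frame(resno = 1:2, resid = "GLY", elety = "CA", chain = "A")
  tr <- frame_series(list(rbind(c(0, 0, 0), c(3, 4, 0))), atoms)
  expect_equal(group_distance_series(tr, "resid 1", "resid 2"), 5)
  expect_equal(group_distance_series(tr, "resid 1", "resid 1"), 0)

  # 4-atom groups against a hand-computed COM distance
  tr2 <- two_group_traj(d = 6.5)
  d <- group_distance_series(tr2, "resid 1", "resid 2")
  expect_equal(d, rep(6.5, 12), tolerance = 1e-9)

  # mass weighting shifts the COM
  m <- c(12, 16, 16, 14, 12, 14, 14)
  dm <- group_distance_series(tr2, "resid 1", "resid 2", masses = m)
  com_a <- colSums(tr2$coords[[1]][1:3, ] * m[1:3]) / sum(m[1:3])
  com_b <- colSums(tr2$coords[[1]][4:7, ] * m[4:7]) / sum(m[4:7])
  expect_equal(dm[1], sqrt(sum((com_a - com_b)^2)), tolerance = 1e-9)
})

test_that("distance distributions are normalised and locate modes", {
  expect_equal(sum(distance_distribution(rep(4, 50), 0.25)$p), 1)
  h1 <- distance_distribution(rep(4, 50), 0.25)
  expect_identical(sum(h1$p > 0), 1L)

  bimodal <- withr::with_seed(11, c(rnorm(4000, 4, 0.15), rnorm(4000, 8, 0.15)))
  h <- distance_distribution(bimodal, 0.25)
  peaks <- h$mid[h$p > 0.5 * max(h$p)]
  expect_true(any(abs(peaks - 4) < 0.25))
  expect_true(any(abs(peaks - 8) < 0.25))
  # mass conserved under bin-width change
  expect_equal(sum(distance_distribution(bimodal, 0.1)$p), 1, tolerance = 1e-12)
})

test_that("salt-bridge occupancy counts frames under the threshold", {
  expect_equal(salt_bridge_occupancy(rep(3.5, 10)), 1)
  expect_equal(salt_bridge_occupancy(rep(8, 10)), 0)
  expect_equal(salt_bridge_occupancy(c(3, 5, 3.9, 4.0, 7)), 3 / 5)
})

test_that("z-density profiles are peak-normalised and shift-equivariant", {
  atoms <- data.frame(resno = 1, resid = "ARG", elety = "CZ", chain = "A")
  tr <- frame_series(replicate(20, matrix(c(1, 2, 10), 1, 3),
                               simplify = FALSE), atoms)
  prof <- z_density_profile(tr, "resid 1", bin_width = 0.5)
  expect_equal(max(prof$density), 1)
  expect_equal(prof$z[which.max(prof$density)], 10.25, tolerance = 0.5)

  g <- gen_toy_trajectory(list(d160_r258 = list(mean = 4, sigma = 0.3),
                               d160_r261 = list(mean = 6, sigma = 0.3)),
                          n_frames = 150, seed = 3)
  p1 <- z_density_profile(g$traj, "resid 258")
  shifted <- g$traj
  shifted$coords <- lapply(shifted$coords, function(m) {
    m[, 3] <- m[, 3] + 5; m
  })
  p2 <- z_density_profile(shifted, "resid 258")
  expect_equal(p2$z, p1$z + 5, tolerance = 1e-9)
  expect_equal(p2$density, p1$density)
})

test_that("Coulomb pair energy follows the screened point-charge law", {
  expect_equal(coulomb_energy(4, 1, -1, epsilon_r = 1),
               -332.0637 / 4, tolerance = 1e-9)
  expect_equal(coulomb_energy(4, 0, -1, epsilon_r = 1), 0)
  e1 <- coulomb_energy(c(3.8, 4.2, 4.0), 1, -1, epsilon_r = 2)
  e2 <- coulomb_energy(c(3.8, 4.2, 4.0), 1, -1, epsilon_r = 4)
  expect_equal(e1, 2 * e2, tolerance = 1e-12)
  # magnitude decreases monotonically with distance
  ds <- seq(3, 10, by = 0.5)
  es <- vapply(ds, function(d) abs(coulomb_energy(d, 1, -1, 4)), numeric(1))
  expect_true(all(diff(es) < 0))
  expect_error(coulomb_energy(c(4, 0), 1, -1, 1), "singular")
})

test_that("cycle energies are consistent, antisymmetric and hand-checkable", {
  t_same <- triad_energy(c(-5, -4, 2), "A_I", "WT")
  t_same_f <- triad_energy(c(-5, -4, 2), "A_F", "WT")
  expect_equal(cycle_energy(t_same, t_same_f, t_same, t_same_f)$dde, 0)
  expect_equal(cycle_energy(t_same, t_same_f, t_same, t_same_f)$de_variant, 0)

  # variant forms two extra 4-Angstrom bridges in the intermediate state
  e_bridge <- coulomb_energy(4, 1, -1, epsilon_r = 4)
  v_ai <- triad_energy(c(e_bridge, e_bridge, 3), "A_I", "N264R")
  v_af <- triad_energy(c(0, 0, 3), "A_F", "N264R")
  r_ai <- triad_energy(c(0, 0, 3), "A_I", "WT")
  r_af <- triad_energy(c(0, 0, 3), "A_F", "WT")
  cyc <- cycle_energy(v_ai, v_af, r_ai, r_af)
  expect_equal(cyc$dde, 2 * e_bridge, tolerance = 1e-9)

  # swapping the state labels negates the transition energies
  v_ai2 <- triad_energy(v_af$pair_energies, "A_I", "N264R")
  v_af2 <- triad_energy(v_ai$pair_energies, "A_F", "N264R")
  cyc2 <- cycle_energy(v_ai2, v_af2, r_ai, r_af)
  expect_equal(cyc2$de_variant, -cyc$de_variant, tolerance = 1e-12)

  expect_error(cycle_energy(v_ai, v_ai, r_ai, r_af), "state labels")
})

test_that("Kabsch superposition recovers rigid transforms", {
  withr::with_seed(5, A <- matrix(rnorm(30), 10, 3))
  id <- kabsch_superpose(A, A)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)

  th <- pi / 2
  R90 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  B <- A %*% t(R90) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, t(R90), tolerance = 1e-9)

  # symmetric in its arguments and cross-checked against bio3d
  withr::with_seed(6, B2 <- A + matrix(rnorm(30, 0, 0.5), 10, 3))
  d_ab <- kabsch_superpose(A, B2)$rmsd
  d_ba <- kabsch_superpose(B2, A)$rmsd
  expect_equal(d_ab, d_ba, tolerance = 1e-10)
  expect_equal(d_ab,
               bio3d::rmsd(as.vector(t(A)), as.vector(t(B2)), fit = TRUE),
               tolerance = 1e-3)

  collinear <- cbind(1:5, 1:5, 1:5)
  expect_error(kabsch_superpose(collinear, collinear + 1), "collinear|degenerate")
})

test_that("frame clustering separates distinct conformations", {
  withr::with_seed(5, A <- matrix(rnorm(30, sd = 3), 10, 3))
  stretched <- A %*% diag(c(2, 0.5, 1))  # genuinely different shape
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  frames <- withr::with_seed(8, c(
    lapply(1:9, function(i) A + matrix(rnorm(30, 0, 0.02), 10, 3)),
    lapply(1:7, function(i) {
      (stretched + matrix(rnorm(30, 0, 0.02), 10, 3)) %*% t(Rz) + 5
    })
  ))
  atoms <- data.frame(resno = 1:10, resid = "GLY", elety = "CA", chain = "A")
  tr <- frame_series(frames, atoms)

  one <- cluster_frames(tr, 1, seed = 2)
  expect_equal(unique(one$labels), 1L)

  two <- cluster_frames(tr, 2, seed = 2)
  expect_identical(length(unique(two$labels[1:9])), 1L)
  expect_identical(length(unique(two$labels[10:16])), 1L)
  expect_false(two$labels[1] == two$labels[16])
  # representative frames come from their own clusters
  expect_equal(two$labels[two$centroid_frames], seq_along(two$sizes))

  # partition content is seed-independent for separated data
  two_b <- cluster_frames(tr, 2, seed = 99)
  expect_true(all((two$labels == two$labels[1]) ==
                    (two_b$labels == two_b$labels[1])))

  expect_error(cluster_frames(tr, 50, seed = 1), "exceeds")
})
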