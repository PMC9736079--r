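test_that("LJ pair energy hits the closed form at the minimum", {
  lj <- load_lj_params()
  crow <- lj[lj$element == "C", ]
  rmin <- 2 * crow$rmin_half
  p <- make_protein(x = 0, y = 0, z = 0, radius = 1.7)
  lig <- make_pose(x = rmin, y = 0, z = 0, radius = 1.7)
  expect_equal(vdw_energy(p, lig, lj), -crow$epsilon_kj, tolerance = 1e-12)
  # beyond cutoff -> 0; far away -> 0
  far <- make_pose(x = 50, y = 0, z = 0)
  expect_equal(vdw_energy(p, far, lj, cutoff = 12), 0)
  # forced overlap is strictly repulsive
  near <- make_pose(x = 1.8, y = 0, z = 0)
  expect_gt(vdw_energy(p, near, lj), 0)
  # near-coincident atoms are an error naming the pair
  clash <- make_pose(x = 0.01, y = 0, z = 0)
  expect_error(vdw_energy(p, clash, lj), "ligand atom 1 and protein atom 1")
})

test_that("LJ sum matches a brute-force pairwise oracle", {
  lj <- load_lj_params()
  p <- make_protein(x = c(0, 3.1, -2.5), y = c(0, 1.2, 0.5),
                    z = c(0, -0.4, 1.1), element = c("C", "N", "O"))
  lig <- make_pose(x = c(4.5, 5.5), y = c(0.3, -1), z = c(0.2, 0.7),
                   element = c("C", "O"))
  brute <- 0
  for (a in 1:3) for (b in 1:2) {
    ea <- p$atoms$element[a]; eb <- lig$atoms$element[b]
    ra <- lj$rmin_half[match(ea, lj$element)]
    rb <- lj$rmin_half[match(eb, lj$element)]
    epsij <- sqrt(lj$epsilon_kj[match(ea, lj$element)] *
                  lj$epsilon_kj[match(eb, lj$element)])
    r <- sqrt(sum((p$atoms[a, c("x", "y", "z")] -
                   lig$atoms[b, c("x", "y", "z")])^2))
    s6 <- ((ra + rb) / r)^6
    brute <- brute + epsij * (s6^2 - 2 * s6)
  }
  expect_equal(vdw_energy(p, lig, lj, cutoff = 1000), brute,
               tolerance = 1e-10)
})

test_that("isolated-sphere SASA matches the analytic area", {
  atoms <- data.frame(x = 0, y = 0, z = 0, radius = 1.7)
  s <- shrake_rupley_sasa(atoms, probe = 1.4, n_sphere_points = 960)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(s$total, sum(s$per_atom))
})

test_that("an enclosed atom has zero accessible area", {
  # central atom caged by 12 large overlapping neighbours
  dirs <- rbind(diag(3), -diag(3),
                cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), 0) / sqrt(2),
                cbind(0, c(1, 1), c(1, -1)) / sqrt(2))
  atoms <- data.frame(x = c(0, 2.2 * dirs[, 1]), y = c(0, 2.2 * dirs[, 2]),
                      z = c(0, 2.2 * dirs[, 3]), radius = c(1.0, rep(2.5, 12)))
  s <- shrake_rupley_sasa(atoms, probe = 1.4, n_sphere_points = 480)
  expect_equal(s$per_atom[1], 0)
})

test_that("touching identical spheres split area symmetrically", {
  atoms <- data.frame(x = c(0, 3.0), y = 0, z = 0, radius = 1.7)
  s <- shrake_rupley_sasa(atoms, probe = 1.4, n_sphere_points = 960)
  expect_equal(s$per_atom[1], s$per_atom[2], tolerance = 0.01)
})

test_that("SASA error against the two-sphere cap formula shrinks with points", {
  cap_total <- function(r1, r2, d, probe) {
    R1 <- r1 + probe; R2 <- r2 + probe
    h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
    h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
    4 * pi * (R1^2 + R2^2) - 2 * pi * (R1 * h1 + R2 * h2)
  }
  atoms <- data.frame(x = c(0, 2.4), y = 0, z = 0, radius = c(1.7, 1.5))
  truth <- cap_total(1.7, 1.5, 2.4, 1.4)
  errs <- vapply(c(120, 960, 7680), function(n)
    abs(shrake_rupley_sasa(atoms, 1.4, n)$total - truth), 0)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("hydrophobic term is the buried-area model", {
  p <- make_protein(x = 0, y = 0, z = 0, radius = 1.7)
  # far ligand: no burial
  far <- make_pose(x = 30, y = 0, z = 0, radius = 1.7)
  expect_equal(hydrophobic_energy(p, far), 0, tolerance = 1e-9)
  # two-sphere toy against the spherical-cap closed form
  lig <- make_pose(x = 4.0, y = 0, z = 0, radius = 1.7)
  gamma <- 0.0226; probe <- 1.4
  R <- 1.7 + probe; d <- 4.0
  h <- R - d / 2  # equal spheres
  buried <- 2 * 2 * pi * R * h
  expect_equal(hydrophobic_energy(p, lig, gamma = gamma, probe = probe,
                                  n_sphere_points = 3840),
               -gamma * buried, tolerance = abs(gamma * buried) * 0.02)
  # deeper burial is more favourable
  deep <- hydrophobic_energy(p, make_pose(x = 3.4, y = 0, z = 0,
                                          radius = 1.7))
  shallow <- hydrophobic_energy(p, make_pose(x = 5.0, y = 0, z = 0,
                                             radius = 1.7))
  expect_lt(deep, shallow)
})

test_that("nonpolar terms are bit-stable on recomputation", {
  p <- make_protein(x = c(0, 2.5), y = 0, z = 0, radius = 1.7)
  lig <- make_pose(x = 4.6, y = 0.4, z = 0.1, radius = 1.7)
  expect_identical(vdw_energy(p, lig), vdw_energy(p, lig))
  expect_identical(hydrophobic_energy(p, lig), hydrophobic_energy(p, lig))
})
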