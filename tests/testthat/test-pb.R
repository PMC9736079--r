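test_that("grid construction follows the fill-fraction rule", {
  p <- make_protein(x = c(0, 7), y = 0, z = 0, radius = 1.7)
  g <- build_grid(p, spacing = 0.6, fill_fraction = 0.7, min_edge = 8)
  # edge 7/0.7 = 10 A; 10/0.6 -> 17 nodes (ceil to odd)
  expect_equal(g$dims, c(17L, 17L, 17L))
  # centroid within h/2 of the grid centre
  centre <- g$origin + (g$dims - 1) / 2 * g$spacing
  expect_lt(max(abs(centre - c(3.5, 0, 0))), g$spacing / 2)
  # smaller fill fraction -> larger box
  g2 <- build_grid(p, spacing = 0.6, fill_fraction = 0.5, min_edge = 8)
  expect_gt(g2$dims[1], g$dims[1])
  # degenerate single-atom extent falls back to the minimum edge
  g3 <- build_grid(make_protein(0, 0, 0), spacing = 0.6,
                   fill_fraction = 0.7, min_edge = 8)
  expect_gte((g3$dims[1] - 1) * 0.6, 8 - 0.6)
})

test_that("dielectric map honours ionic strength, sources, conservation", {
  p <- make_protein(x = c(0, 2.5), y = 0, z = 0, radius = 1.7,
                    charge = c(0.5, -0.25))
  g <- build_grid(p, spacing = 0.5, fill_fraction = 0.5, min_edge = 10)
  m0 <- map_dielectric(p, g, ionic_strength = 0)
  expect_true(all(m0$kappa2 == 0))
  m <- map_dielectric(p, g, ionic_strength = 0.145)
  expect_gt(max(m$kappa2), 0)
  # kappa2 is zero inside solute and Stern layer
  expect_true(any(m$kappa2 == 0))
  expect_setequal(unique(as.numeric(m$epsx)), c(2, 80))
  # total mapped source charge equals the total protein charge
  expect_equal(sum(m$source), 0.25, tolerance = 1e-6)
})

test_that("an on-node charge maps to a single node", {
  p <- make_protein(x = 0, y = 0, z = 0, radius = 1.7, charge = 1)
  g <- build_grid(p, spacing = 0.5, fill_fraction = 0.5, min_edge = 10)
  m <- map_dielectric(p, g)
  expect_equal(max(m$source), 1, tolerance = 1e-12)
  expect_equal(sum(m$source != 0), 1)
})

test_that("zero charges give an identically zero potential", {
  g <- structure(list(origin = c(-3, -3, -3), spacing = 0.6,
                      dims = c(11L, 11L, 11L)), class = "grid_spec")
  m <- uniform_map(g, data.frame(x = 0, y = 0, z = 0, q = 0))
  pot <- solve_lpbe(m)
  expect_true(all(pot$phi == 0))
})

test_that("point-charge potential matches the screened-Coulomb closed form", {
  bench <- dh_benchmark(spacing = 0.6)
  err <- dh_max_rel_err(bench, rmin = 1.8)
  expect_lt(err, 0.02)
})

test_that("discretization error decreases as the grid is refined", {
  errs <- vapply(c(0.9, 0.6, 0.45), function(h)
    dh_max_rel_err(dh_benchmark(spacing = h), rmin = 1.8), 0)
  expect_true(all(diff(errs) < 0))
})

test_that("with no screening the solution reduces to Coulomb", {
  bench <- dh_benchmark(spacing = 0.6, I = 0)
  err <- dh_max_rel_err(bench, rmin = 1.8)
  expect_lt(err, 0.02)
})

test_that("the linearized solution superposes", {
  n <- 21L
  g <- structure(list(origin = rep(-(n - 1) / 2 * 0.6, 3), spacing = 0.6,
                      dims = c(n, n, n)), class = "grid_spec")
  chA <- data.frame(x = -1.2, y = 0, z = 0, q = 1)
  chB <- data.frame(x = 1.8, y = 0.6, z = -0.6, q = -0.7)
  pA <- solve_lpbe(uniform_map(g, chA), tol = 1e-8)
  pB <- solve_lpbe(uniform_map(g, chB), tol = 1e-8)
  pAB <- solve_lpbe(uniform_map(g, rbind(chA, chB)), tol = 1e-8)
  expect_equal(pAB$phi, pA$phi + pB$phi, tolerance = 1e-5)
})

test_that("repeated solves are bit-stable", {
  p <- make_protein(x = c(0, 2.5), y = 0, z = 0, radius = 1.7,
                    charge = c(0.5, -0.5))
  g <- build_grid(p, spacing = 0.6, fill_fraction = 0.5, min_edge = 10)
  m <- map_dielectric(p, g)
  s1 <- solve_lpbe(m)
  s2 <- solve_lpbe(m)
  expect_identical(s1$phi, s2$phi)
})

test_that("grid translation leaves interpolated site potentials unchanged", {
  shift <- c(0.23, -0.11, 0.37)
  p1 <- make_protein(x = c(0, 2.5), y = c(0, 0.5), z = 0, radius = 1.7,
                     charge = c(0.5, -0.5))
  p2 <- make_protein(x = c(0, 2.5) + shift[1], y = c(0, 0.5) + shift[2],
                     z = shift[3], radius = 1.7, charge = c(0.5, -0.5))
  site1 <- matrix(c(1.25, 1.5, 0.4), 1)
  pot1 <- solve_lpbe(map_dielectric(p1, build_grid(p1, 0.6, 0.5,
                                                   min_edge = 10)))
  pot2 <- solve_lpbe(map_dielectric(p2, build_grid(p2, 0.6, 0.5,
                                                   min_edge = 10)))
  phi1 <- interpolate_esp(pot1, site1)
  phi2 <- interpolate_esp(pot2, site1 + rep(shift, each = 1))
  expect_equal(phi1, phi2, tolerance = 1e-6)
})

test_that("trilinear interpolation is exact at nodes and for linear fields", {
  n <- 9L
  g <- structure(list(origin = c(0, 0, 0), spacing = 0.5,
                      dims = c(n, n, n)), class = "grid_spec")
  ax <- (seq_len(n) - 1) * 0.5
  lin <- function(x, y, z) 2 + 3 * x - 1.5 * y + 0.25 * z
  phi <- array(0, c(n, n, n))
  for (k in 1:n) for (j in 1:n) for (i in 1:n)
    phi[i, j, k] <- lin(ax[i], ax[j], ax[k])
  pot <- structure(list(grid = g, phi = phi, units = "kT/e",
                        temperature = 298.15), class = "potential_grid")
  # scale factor between stored and returned units from a node value
  scale <- interpolate_esp(pot, matrix(c(0, 0, 0), 1)) / lin(0, 0, 0)
  # exact at an interior node
  expect_equal(interpolate_esp(pot, matrix(c(1, 1.5, 2), 1)),
               scale * lin(1, 1.5, 2), tolerance = 1e-12)
  # exact for arbitrary interior sites because the field is linear
  sites <- matrix(c(0.61, 1.11, 3.07,
                    2.2, 0.35, 1.81), 2, byrow = TRUE)
  expect_equal(interpolate_esp(pot, sites),
               as.numeric(scale) * lin(sites[, 1], sites[, 2], sites[, 3]),
               tolerance = 1e-10)
  # cell centre equals the mean of the 8 corner values
  corner_mean <- mean(phi[1:2, 1:2, 1:2])
  expect_equal(interpolate_esp(pot, matrix(c(0.25, 0.25, 0.25), 1)),
               as.numeric(scale) * corner_mean, tolerance = 1e-10)
  # outside sites are an error naming the offender
  expect_error(interpolate_esp(pot, matrix(c(-1, 0, 0), 1)), "site 1")
})

test_that("site interaction energy is the charge-weighted potential sum", {
  expect_equal(electrostatic_interaction_energy(c(2, -1), c(0, 0)), 0)
  expect_equal(electrostatic_interaction_energy(2.0, 1.0), 2.0)
  phi <- c(1.5, -2, 0.3); q <- c(0.1, 0.2, -0.4)
  expect_equal(electrostatic_interaction_energy(phi, 2 * q),
               2 * electrostatic_interaction_energy(phi, q))
  expect_equal(electrostatic_interaction_energy(phi, q), sum(phi * q))
  expect_error(electrostatic_interaction_energy(c(1, 2), 1), "mismatch")
})
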