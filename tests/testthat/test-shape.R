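test_that("radial surface sampling matches analytic expectations", {
  quad <- sphere_quadrature(8, 16)
  # single sphere centred at the centroid: all samples equal its radius
  one <- data.frame(x = 1, y = 2, z = 3, radius = 2.2)
  r <- radial_shape_function(one, c(1, 2, 3), quad$dirs)
  expect_equal(r, rep(2.2, nrow(quad$dirs)), tolerance = 1e-12)
  # two spheres symmetric about the centroid: reflection symmetry
  dumb <- data.frame(x = c(-1, 1), y = 0, z = 0, radius = 1.2)
  rd <- radial_shape_function(dumb, c(0, 0, 0), quad$dirs)
  rd_ref <- radial_shape_function(dumb, c(0, 0, 0), -quad$dirs)
  expect_equal(rd, rd_ref, tolerance = 1e-12)
  expect_error(radial_shape_function(dumb[0, ], c(0, 0, 0), quad$dirs),
               "empty")
})

test_that("radial samples agree with a bisection ray-marching oracle", {
  atoms <- data.frame(x = c(-0.8, 0.9, 0), y = c(0, 0.2, -0.3),
                      z = c(0.1, -0.2, 0.5), radius = c(1.4, 1.1, 1.6))
  centroid <- colMeans(atoms[, 1:3])
  quad <- sphere_quadrature(6, 12)
  mine <- radial_shape_function(atoms, centroid, quad$dirs)
  inside <- function(p) any((p[1] - atoms$x)^2 + (p[2] - atoms$y)^2 +
                            (p[3] - atoms$z)^2 <= atoms$radius^2 + 1e-14)
  oracle <- vapply(seq_len(nrow(quad$dirs)), function(i) {
    d <- quad$dirs[i, ]
    # march out to bracket the boundary, then bisect
    t_hi <- 10
    while (inside(centroid + t_hi * d)) t_hi <- t_hi * 2
    t_lo <- 0
    # find the outermost inside point by fine scan, then bisect
    ts <- seq(0, t_hi, by = 1e-3)
    ins <- vapply(ts, function(t) inside(centroid + t * d), TRUE)
    t_lo <- ts[max(which(ins))]
    t_hi <- t_lo + 1e-3
    for (b in 1:60) {
      mid <- (t_lo + t_hi) / 2
      if (inside(centroid + mid * d)) t_lo <- mid else t_hi <- mid
    }
    (t_lo + t_hi) / 2
  }, 0)
  expect_equal(mine, oracle, tolerance = 1e-9)
})

test_that("a sphere expands to pure degree zero", {
  quad <- sphere_quadrature(16, 32)
  d <- sh_expand(rep(2, nrow(quad$dirs)), quad$dirs, l_max = 6,
                 weights = quad$weights)
  expect_equal(d$c_l[1], 2 * sqrt(4 * pi), tolerance = 1e-9)
  expect_lt(max(d$c_l[-1]), 1e-9)
})

test_that("descriptors are rotation-invariant", {
  # smooth star-shaped body: big sphere plus an interior off-centre atom
  # (shifts the centroid, making the radial function non-trivial)
  atoms <- data.frame(x = c(0, 0.9), y = c(0, 0.4), z = c(0, 0.1),
                      radius = c(3, 0.4))
  d0 <- shape_descriptor(atoms, l_max = 6)
  R <- rotation_matrix(c(1, 2, 0.5), 1.1)
  d1 <- shape_descriptor(rotate_atoms(atoms, R), l_max = 6)
  expect_lt(max(abs(d0$c_l - d1$c_l)), 1e-6)
  R2 <- rotation_matrix(c(-0.3, 1, 2), 2.7)
  d2 <- shape_descriptor(rotate_atoms(atoms, R2), l_max = 6)
  expect_lt(max(abs(d0$c_l - d2$c_l)), 1e-6)
})

test_that("descriptors are translation-independent", {
  atoms <- data.frame(x = c(0, 0.9), y = c(0, 0.4), z = c(0, 0.1),
                      radius = c(3, 0.4))
  moved <- atoms
  moved$x <- moved$x + 5; moved$y <- moved$y - 2; moved$z <- moved$z + 0.7
  expect_equal(shape_descriptor(atoms)$c_l, shape_descriptor(moved)$c_l,
               tolerance = 1e-10)
})

test_that("a centrosymmetric dumbbell is even-degree dominated", {
  dumb <- data.frame(x = c(-1, 1), y = 0, z = 0, radius = 1.5)
  d <- shape_descriptor(dumb, l_max = 6)
  expect_gt(d$c_l[3], d$c_l[2])  # c_2 > c_1
  expect_lt(d$c_l[2] / d$c_l[1], 1e-6)  # odd degrees vanish
})

test_that("shape distance is a metric on descriptor vectors", {
  s2 <- shape_descriptor(data.frame(x = 0, y = 0, z = 0, radius = 2))
  s3 <- shape_descriptor(data.frame(x = 0, y = 0, z = 0, radius = 3))
  expect_equal(shape_distance(s2, s2), 0)
  expect_equal(shape_distance(s2, s3), sqrt(4 * pi), tolerance = 1e-6)
  expect_equal(shape_distance(s2, s3), 3.5449, tolerance = 1e-4)
  expect_equal(shape_distance(s2, s3), shape_distance(s3, s2))
  # triangle inequality over random star-shaped triples
  set.seed(42)
  rand_desc <- function() {
    n <- 3
    atoms <- data.frame(x = c(0, runif(n, -1, 1)),
                        y = c(0, runif(n, -1, 1)),
                        z = c(0, runif(n, -1, 1)),
                        radius = c(2.5, runif(n, 0.5, 1.2)))
    shape_descriptor(atoms)
  }
  for (rep in 1:8) {
    a <- rand_desc(); b <- rand_desc(); c <- rand_desc()
    expect_lte(shape_distance(a, c),
               shape_distance(a, b) + shape_distance(b, c) + 1e-12)
  }
  d5 <- shape_descriptor(data.frame(x = 0, y = 0, z = 0, radius = 2),
                         l_max = 4)
  expect_error(shape_distance(s2, d5), "l_max")
})

test_that("protomol fills the pocket and responds to protein crowding", {
  ref <- make_pose(x = c(-0.5, 0.5), y = 0, z = 0, radius = 1.7)
  empty <- make_protein(numeric(0), numeric(0), numeric(0))
  pm0 <- generate_protomol(empty, ref, pocket_radius = 6, grid_step = 1)
  # with no protein every lattice point in the sphere is a probe
  g <- seq(-6, 6, by = 1)
  lattice <- expand.grid(x = g, y = g, z = g)
  expect_equal(nrow(pm0$atoms), sum(rowSums(lattice^2) <= 36))
  # probes never sit inside protein atoms, and crowding shrinks the protomol
  prot1 <- make_protein(x = 3, y = 0, z = 0, radius = 1.7)
  pm1 <- generate_protomol(prot1, ref, pocket_radius = 6, grid_step = 1)
  expect_lt(nrow(pm1$atoms), nrow(pm0$atoms))
  d <- sqrt((pm1$atoms$x - 3)^2 + pm1$atoms$y^2 + pm1$atoms$z^2)
  expect_true(all(d >= 1.7 + pm1$probe_radius - 1e-9))
  prot2 <- make_protein(x = c(3, -3), y = 0, z = 0, radius = 1.7)
  pm2 <- generate_protomol(prot2, ref, pocket_radius = 6, grid_step = 1)
  expect_lt(nrow(pm2$atoms), nrow(pm1$atoms))
})

test_that("protomol probes match an exhaustive lattice-scan oracle", {
  sys <- make_toy_system(fixture_spec(seed = 2, n_actives = 1,
                                      n_inverted = 1, n_scrambled = 1))
  prot <- assign_radii(sys$protein)
  pm <- generate_protomol(prot, sys$cognate, pocket_radius = 8,
                          grid_step = 1.2, probe_radius = 1.7, reach = 5)
  cen <- colMeans(as.matrix(sys$cognate$atoms[, c("x", "y", "z")]))
  g <- seq(-8, 8, by = 1.2)
  lattice <- as.matrix(expand.grid(x = g, y = g, z = g))
  lattice <- sweep(lattice, 2, -cen)
  keep <- rowSums(sweep(lattice, 2, cen)^2) <= 64
  ok <- logical(nrow(lattice)); ok[keep] <- TRUE
  near <- logical(nrow(lattice))
  for (a in seq_len(nrow(prot$atoms))) {
    d2 <- (lattice[, 1] - prot$atoms$x[a])^2 +
          (lattice[, 2] - prot$atoms$y[a])^2 +
          (lattice[, 3] - prot$atoms$z[a])^2
    ok <- ok & d2 >= (prot$atoms$radius[a] + 1.7)^2
    near <- near | d2 <= (prot$atoms$radius[a] + 1.7 + 5)^2
  }
  oracle <- lattice[keep & ok & near, , drop = FALSE]
  expect_equal(nrow(pm$atoms), nrow(oracle))
  expect_equal(as.matrix(pm$atoms[, c("x", "y", "z")]), oracle,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("an empty pocket region reproduces the reference-sphere shape", {
  ref <- make_pose(x = 0, y = 0, z = 0, radius = 1.7)
  empty <- make_protein(numeric(0), numeric(0), numeric(0))
  pm <- generate_protomol(empty, ref, pocket_radius = 5, grid_step = 0.5)
  d_pm <- shape_descriptor(pm$atoms, l_max = 4)
  # lattice ball of radius 5 + probe radius: compare against the sphere
  ball <- shape_descriptor(data.frame(x = 0, y = 0, z = 0,
                                      radius = 5 + 1.7), l_max = 4)
  expect_lt(shape_distance(d_pm, ball), 0.05 * ball$c_l[1])
})
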