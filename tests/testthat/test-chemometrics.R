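prep <- function(pose) assign_radii(gasteiger_charges(pose))

test_that("methane has no donors/acceptors and a vanishing dipole", {
  d <- compute_descriptors(prep(make_methane()))
  expect_equal(d$hba, 0)
  expect_equal(d$hbd, 0)
  expect_lt(d$dipole, 1e-9)
  expect_gt(d$sasa, 0)
  expect_gt(d$volume, 0)
  expect_true(d$proxy_ea_ip)
})

test_that("water counts one donor per O-H and at least one acceptor", {
  d <- compute_descriptors(prep(make_water()))
  expect_equal(d$hbd, 2)
  expect_gte(d$hba, 1)
  expect_gt(d$dipole, 0.5)  # polar molecule
})

test_that("a single united sphere is maximally globular", {
  pose <- assign_radii(make_pose(x = 0, y = 0, z = 0, element = "C",
                                 charge = 0))
  d <- compute_descriptors(pose, volume_step = 0.2)
  expect_gte(d$globularity, 0.98)
  expect_lte(d$globularity, 1)
  # an elongated chain is less globular
  chain <- assign_radii(make_pose(x = c(0, 3, 6, 9), y = 0, z = 0,
                                  element = "C", charge = 0))
  expect_lt(compute_descriptors(chain)$globularity, d$globularity)
})

test_that("descriptors demand charges before computing the dipole", {
  pose <- assign_radii(make_methane())
  expect_error(compute_descriptors(pose), "charge")
})

test_that("descriptor similarity follows the min/max rule", {
  ref <- structure(list(hba = 2, hbd = 1, dipole = 1.5,
                        electron_affinity = 1.2, globularity = 0.8,
                        ionization_potential = 11, sasa = 200, volume = 150,
                        proxy_ea_ip = TRUE), class = "descriptor_vector")
  expect_true(all(descriptor_similarity(ref, ref) == 1))
  q <- ref; q$sasa <- 100
  s <- descriptor_similarity(ref, q)
  expect_equal(unname(s["sasa"]), 0.5)
  # both-zero degenerate case scores 1; sign mismatch scores 0
  r0 <- ref; r0$dipole <- 0
  q0 <- ref; q0$dipole <- 0
  expect_equal(unname(descriptor_similarity(r0, q0)["dipole"]), 1)
  qn <- ref; qn$dipole <- -1.5
  expect_equal(unname(descriptor_similarity(ref, qn)["dipole"]), 0)
  # symmetry
  expect_equal(descriptor_similarity(ref, q), descriptor_similarity(q, ref))
})

test_that("atom pairs enumerate typed shortest-path features", {
  ethane <- make_pose(x = c(0, 1.54, -0.6, -0.6, 2.1, 2.1),
                      y = c(0, 0, 0.9, -0.9, 0.9, -0.9), z = 0,
                      element = c("C", "C", "H", "H", "H", "H"),
                      bonds = data.frame(i = c(1L, 1L, 1L, 2L, 2L),
                                         j = c(2L, 3L, 4L, 5L, 6L),
                                         order = 1L))
  fp <- atom_pair_fingerprint(ethane)
  expect_length(fp, 1)
  expect_equal(unname(as.integer(fp)), 1)
  propane <- make_pose(x = c(0, 1.5, 3), y = c(0, 0.8, 0), z = 0,
                       element = "C",
                       bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                          order = 1L))
  fp2 <- atom_pair_fingerprint(propane)
  # distances 1 (x2) and 2 (x1)
  expect_equal(sum(fp2), 3)
  # binary mode clamps counts to presence
  expect_true(all(atom_pair_fingerprint(propane, counted = FALSE) == 1))
  d1 <- fp2[grepl("\\|1$", names(fp2))]
  d2 <- fp2[grepl("\\|2$", names(fp2))]
  expect_equal(sum(d1), 2)
  expect_equal(sum(d2), 1)
})

test_that("fingerprints are invariant to atom reordering", {
  pose <- make_pose(x = c(0, 1.5, 3, 1.5), y = c(0, 0.8, 0, 2.2), z = 0,
                    element = c("C", "C", "O", "N"),
                    bonds = data.frame(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                                       order = c(1L, 2L, 1L)))
  perm <- c(3L, 1L, 4L, 2L)  # new position of each old atom
  atoms2 <- pose$atoms[order(perm), ]
  bonds2 <- data.frame(i = perm[pose$bonds$i], j = perm[pose$bonds$j],
                       order = pose$bonds$order)
  pose2 <- make_pose(x = atoms2$x, y = atoms2$y, z = atoms2$z,
                     element = atoms2$element, bonds = bonds2)
  f1 <- atom_pair_fingerprint(pose)
  f2 <- atom_pair_fingerprint(pose2)
  expect_equal(sort(names(f1)), sort(names(f2)))
  expect_equal(as.integer(f1[sort(names(f1))]),
               as.integer(f2[sort(names(f2))]))
})

test_that("molecular weight sums standard atomic masses", {
  expect_equal(molecular_weight(make_methane()), 12.011 + 4 * 1.008,
               tolerance = 1e-9)
  expect_equal(molecular_weight(make_water()), 18.015, tolerance = 1e-3)
  expect_error(molecular_weight(make_pose(0, 0, 0, element = "Xx")), "Xx")
})

test_that("count-Tanimoto follows sum-min over sum-max", {
  a <- structure(setNames(c(1L, 1L, 1L, 1L), paste0("f", 1:4)),
                 class = "atom_pair_fingerprint")
  b <- structure(setNames(rep(1L, 6), paste0("f", 2:7)),
                 class = "atom_pair_fingerprint")
  expect_equal(tanimoto(a, b), 3 / 7, tolerance = 1e-12)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  disj <- structure(setNames(c(2L), "g1"), class = "atom_pair_fingerprint")
  expect_equal(tanimoto(a, disj), 0)
  e <- structure(integer(0), class = "atom_pair_fingerprint")
  expect_warning(t1 <- tanimoto(e, e), "empty")
  expect_equal(t1, 1)
})
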