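# Seedable synthetic pocket/ligand systems: a ring cavity of charged
# pseudo-atoms, a cognate ligand whose charge pattern complements the
# pocket, and decoy classes (charge-inverted, shape-perturbed, scrambled)
# reproducing the statistical structure that electrostatic rescoring
# exploits -- near-identical geometry, differing charge patterns.

#' Specification of a synthetic toy system
#'
#' The pocket is two stacked rings of charged carbon pseudo-atoms around a
#' central cavity; the cognate is an interior atom ring whose alternating
#' charges complement the pocket columns. Decoy classes: `inverted` (same
#' geometry, negated charges), `perturbed` (jittered geometry, same
#' charges), `scrambled` (jittered geometry, spatially permuted charges).
#' Actives are small-jitter copies of the cognate.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_ring Pocket pseudo-atoms (split over two rings).
#' @param ring_radius,ring_z Pocket ring radius and half-separation,
#'   Angstrom.
#' @param pocket_charge Magnitude of the alternating pocket charges, e.
#' @param n_ligand_atoms Number of charged cognate atoms (even); a neutral
#'   central atom is added so the surface is star-shaped about the centroid.
#' @param ligand_radius Cognate ring radius, Angstrom.
#' @param ligand_z Half-separation of the two interleaved cognate rings.
#' @param ligand_charge Magnitude of the balanced cognate charges, e.
#' @param n_actives,n_inverted,n_perturbed,n_scrambled Class counts.
#' @param sigma_active,sigma_perturb,sigma_scramble Coordinate jitter SDs,
#'   Angstrom.
#' @return `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_ring = 16, ring_radius = 6,
                         ring_z = 2, pocket_charge = 0.4,
                         n_ligand_atoms = 8, ligand_radius = 2,
                         ligand_z = 0.6, ligand_charge = 0.35,
                         n_actives = 5, n_inverted = 25, n_perturbed = 0,
                         n_scrambled = 20,
                         sigma_active = 0.1, sigma_perturb = 0.3,
                         sigma_scramble = 0.6) {
  if (n_ring %% 2 || n_ligand_atoms %% 2)
    stop("n_ring and n_ligand_atoms must be even")
  spec <- as.list(environment())
  class(spec) <- "fixture_spec"
  spec
}

.fixture_pocket <- function(spec) {
  half <- spec$n_ring / 2L
  ang <- 2 * pi * (seq_len(half) - 1) / half
  ring <- function(z, chain) data.frame(
    element = "C",
    x = spec$ring_radius * cos(ang), y = spec$ring_radius * sin(ang),
    z = z, radius = NA_real_,
    charge = spec$pocket_charge * (-1)^(seq_len(half) - 1),
    atom_name = ifelse((-1)^(seq_len(half) - 1) > 0, "CP", "CN"),
    resid = "GLY", resno = seq_len(half) + if (chain == "B") half else 0L,
    chain = chain, is_metal = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(ring(spec$ring_z, "A"), ring(-spec$ring_z, "B"))
  structure(list(atoms = atoms, source = "fixture"),
            class = "protein_structure")
}

# Cognate template: n charged atoms on two interleaved rings inside the
# cavity plus one neutral central atom (guaranteeing a star-shaped surface).
# Charges are electrostatically complementary to the pocket by construction:
# the ligand-free pocket potential is solved once and the balanced +-q
# pattern is placed against it (negative charges at the most positive
# sites), making the cognate a near-optimal binder that charge-inverted and
# charge-permuted decoys degrade from.
.fixture_cognate <- function(spec, pocket, radii, pb = es_defaults()$pb) {
  n <- spec$n_ligand_atoms
  ang <- 2 * pi * (seq_len(n) - 1) / n
  atoms <- data.frame(
    element = "C",
    x = c(spec$ligand_radius * cos(ang), 0),
    y = c(spec$ligand_radius * sin(ang), 0),
    z = c(spec$ligand_z * (-1)^(seq_len(n) - 1), 0),
    radius = NA_real_, charge = 0, stringsAsFactors = FALSE)
  prot <- assign_radii(pocket, radii)
  grid <- build_grid(prot, spacing = pb$spacing, fill_fraction = pb$fill,
                     min_edge = pb$min_edge)
  dmap <- map_dielectric(prot, grid, eps_in = pb$eps_in,
                         eps_out = pb$eps_out,
                         ionic_strength = pb$ionic_strength,
                         ion_radius = pb$ion_radius, probe = pb$probe,
                         temperature = pb$temperature)
  pot <- solve_lpbe(dmap, omega = pb$omega, tol = pb$tol, maxit = pb$maxit)
  phi <- interpolate_esp(pot, as.matrix(atoms[seq_len(n), c("x", "y", "z")]))
  q <- numeric(n)
  o <- order(phi)  # most negative potential first
  q[o[seq_len(n / 2)]] <- spec$ligand_charge
  q[o[(n / 2 + 1):n]] <- -spec$ligand_charge
  atoms$charge <- c(q, 0)
  bonds <- data.frame(i = c(seq_len(n), n + 1L),
                      j = c(seq_len(n)[-1], 1L, 1L),
                      order = 1L)
  .new_ligand_pose("cognate", atoms, bonds, 0L)
}

.min_clearance <- function(pocket, pose, radii) {
  P <- as.matrix(pocket$atoms[, c("x", "y", "z")])
  L <- as.matrix(pose$atoms[, c("x", "y", "z")])
  rp <- radii[["C"]]
  mind <- Inf
  for (a in seq_len(nrow(L))) {
    d <- sqrt((P[, 1] - L[a, 1])^2 + (P[, 2] - L[a, 2])^2 +
              (P[, 3] - L[a, 3])^2)
    mind <- min(mind, min(d) - 2 * rp)
  }
  mind
}

#' Generate a synthetic pocket + ligand-library system
#'
#' Writes a protein PDB, cognate SDF, library SDF, a matching protein charge
#' table (TSV), and a ground-truth manifest (JSON). Jittered ligands that
#' clash with the pocket are regenerated (up to `max_attempts`); byte-
#' identical outputs for identical seeds.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if missing).
#' @param max_attempts Clash-regeneration attempts per ligand.
#' @return List with file `paths`, the `manifest`, and the in-memory
#'   `protein`, `cognate`, and `library` objects.
#' @export
make_toy_system <- function(spec, dir = tempfile("toysys"),
                            max_attempts = 25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  radii <- load_radius_set()
  pocket <- .fixture_pocket(spec)
  cognate <- .fixture_cognate(spec, pocket, radii)
  if (.min_clearance(pocket, cognate, radii) < 0)
    stop("fixture_spec geometry places the cognate in steric clash")

  jitter_pose <- function(base, name, sigma, permute_charges = FALSE,
                          invert = FALSE) {
    for (attempt in seq_len(max_attempts)) {
      p <- base
      p$name <- name
      n <- nrow(p$atoms)
      if (sigma > 0) {
        p$atoms$x <- p$atoms$x + rnorm(n, 0, sigma)
        p$atoms$y <- p$atoms$y + rnorm(n, 0, sigma)
        p$atoms$z <- p$atoms$z + rnorm(n, 0, sigma)
      }
      if (permute_charges) p$atoms$charge <- sample(p$atoms$charge)
      if (invert) p$atoms$charge <- -p$atoms$charge
      ok <- .min_clearance(pocket, p, radii) >= 0.1
      if (ok) {
        # the shape module needs a star-shaped surface about the centroid
        pr <- assign_radii(p, radii)
        quad <- sphere_quadrature(16, 32)
        cen <- colMeans(as.matrix(pr$atoms[, c("x", "y", "z")]))
        ok <- !inherits(try(radial_shape_function(pr$atoms, cen, quad$dirs),
                            silent = TRUE), "try-error")
      }
      if (ok) return(p)
    }
    stop("could not place ligand '", name, "' without clashes after ",
         max_attempts, " attempts")
  }

  lib <- list()
  labels <- logical(0)
  classes <- character(0)
  add <- function(pose, active, cls) {
    lib[[length(lib) + 1]] <<- pose
    labels <<- c(labels, active)
    classes <<- c(classes, cls)
  }
  for (i in seq_len(spec$n_actives))
    add(jitter_pose(cognate, sprintf("active_%02d", i), spec$sigma_active),
        TRUE, "active")
  for (i in seq_len(spec$n_inverted))
    add(jitter_pose(cognate, sprintf("inverted_%02d", i), 0, invert = TRUE),
        FALSE, "inverted")
  for (i in seq_len(spec$n_perturbed))
    add(jitter_pose(cognate, sprintf("perturbed_%02d", i),
                    spec$sigma_perturb), FALSE, "perturbed")
  for (i in seq_len(spec$n_scrambled))
    add(jitter_pose(cognate, sprintf("scrambled_%02d", i),
                    spec$sigma_scramble, permute_charges = TRUE),
        FALSE, "scrambled")

  paths <- list(protein = file.path(dir, "pocket.pdb"),
                cognate = file.path(dir, "cognate.sdf"),
                library = file.path(dir, "library.sdf"),
                charge_table = file.path(dir, "pocket_charges.tsv"),
                manifest = file.path(dir, "manifest.json"))
  pa <- pocket$atoms
  bio3d::write.pdb(pdb = NULL, file = paths$protein,
                   xyz = as.numeric(t(as.matrix(pa[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(pa)), resno = pa$resno,
                   resid = pa$resid, eleno = seq_len(nrow(pa)),
                   elety = pa$atom_name, chain = pa$chain,
                   elesy = pa$element, o = rep(1, nrow(pa)),
                   b = rep(0, nrow(pa)))
  write_ligand_poses(cognate, paths$cognate)
  write_ligand_poses(lib, paths$library)
  write.table(data.frame(residue = "GLY", atom = c("CP", "CN"),
                         charge = c(spec$pocket_charge,
                                    -spec$pocket_charge)),
              paths$charge_table, sep = "\t", row.names = FALSE,
              quote = FALSE)

  rmsd <- vapply(lib, function(p)
    sqrt(mean(rowSums((as.matrix(p$atoms[, c("x", "y", "z")]) -
                       as.matrix(cognate$atoms[, c("x", "y",
                                                   "z")]))^2))), 0)
  manifest <- list(
    seed = spec$seed,
    pocket = list(n_atoms = nrow(pa),
                  per_chain = as.list(table(pa$chain)),
                  charges = pa$charge),
    cognate = list(n_atoms = nrow(cognate$atoms),
                   charges = cognate$atoms$charge),
    ligands = data.frame(name = vapply(lib, `[[`, "", "name"),
                         class = classes, active = labels,
                         net_charge = vapply(lib, function(p)
                           sum(p$atoms$charge), 0),
                         rmsd_to_cognate = rmsd,
                         stringsAsFactors = FALSE),
    expected_ordering = "actives > decoys by electrostatic replacement")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  list(paths = paths, manifest = manifest, protein = pocket,
       cognate = cognate, library = lib,
       labels = data.frame(name = manifest$ligands$name,
                           active = labels, stringsAsFactors = FALSE))
}

#' Synthetic scored benchmark ranking
#'
#' Scores drawn from two unit-variance normal distributions separated by
#' `separation`; the expected AUC is the binormal closed form
#' `pnorm(separation / sqrt(2))`.
#'
#' @param seed Integer seed.
#' @param n_actives,n_decoys Class sizes.
#' @param separation Effect size (difference of means).
#' @return `labeled_ranking`.
#' @export
make_scored_benchmark <- function(seed, n_actives, n_decoys, separation) {
  stopifnot(n_actives >= 1, n_decoys >= 1)
  set.seed(seed)
  scores <- c(rnorm(n_actives, separation, 1), rnorm(n_decoys, 0, 1))
  labeled_ranking(
    c(sprintf("act_%04d", seq_len(n_actives)),
      sprintf("dec_%04d", seq_len(n_decoys))),
    scores, c(rep(TRUE, n_actives), rep(FALSE, n_decoys)))
}
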