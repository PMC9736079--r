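# Nonpolar interaction terms: 12-6 Lennard-Jones protein-ligand energy and
# a buried solvent-accessible-surface-area hydrophobic term. Both are
# single-point (no minimization) and reported in kJ/mol.

#' Load per-element Lennard-Jones parameters
#'
#' TSV with columns `element`, `epsilon_kj` (well depth, kJ/mol) and
#' `rmin_half` (half the minimum-energy pair distance, Angstrom). The
#' packaged defaults are a general force-field element table. Combination
#' rules: arithmetic for r_min, geometric for epsilon.
#'
#' @param path TSV path.
#' @return data.frame of class `lj_params`.
#' @export
load_lj_params <- function(path = .extdata("lj_params.tsv")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("element", "epsilon_kj", "rmin_half") %in% names(tab)))
    stop("LJ table needs columns element, epsilon_kj, rmin_half")
  if (any(tab$epsilon_kj <= 0) || any(tab$rmin_half <= 0))
    stop("LJ parameters must be positive")
  class(tab) <- c("lj_params", class(tab))
  tab
}

#' Protein-ligand van der Waals energy
#'
#' Sum over protein-ligand atom pairs within `cutoff` of the 12-6 potential
#' `eps_ij [ (rmin_ij/r)^12 - 2 (rmin_ij/r)^6 ]` with `rmin_ij` the sum of
#' the two half-r_min values and `eps_ij` the geometric mean of the well
#' depths. Near-coincident atoms (r < 0.1 A) are an error naming the pair.
#'
#' @param protein `protein_structure`.
#' @param ligand `ligand_pose`.
#' @param params [load_lj_params()] table.
#' @param cutoff Pair distance cutoff, Angstrom.
#' @return Energy in kJ/mol.
#' @export
vdw_energy <- function(protein, ligand, params = load_lj_params(),
                       cutoff = 12) {
  look <- function(el) {
    ix <- match(el, params$element)
    if (any(is.na(ix)))
      stop("no LJ parameters for element(s): ",
           paste(unique(el[is.na(ix)]), collapse = ", "))
    ix
  }
  ip <- look(protein$atoms$element)
  il <- look(ligand$atoms$element)
  P <- as.matrix(protein$atoms[, c("x", "y", "z")])
  L <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  e <- 0
  for (a in seq_len(nrow(L))) {
    d2 <- (P[, 1] - L[a, 1])^2 + (P[, 2] - L[a, 2])^2 + (P[, 3] - L[a, 3])^2
    if (any(d2 < 0.01)) {
      b <- which(d2 < 0.01)[1]
      stop(sprintf(
        "overlapping atoms: ligand atom %d and protein atom %d (r = %.3f A)",
        a, b, sqrt(d2[b])))
    }
    sel <- which(d2 <= cutoff^2)
    if (!length(sel)) next
    rmin <- params$rmin_half[ip[sel]] + params$rmin_half[il[a]]
    epsij <- sqrt(params$epsilon_kj[ip[sel]] * params$epsilon_kj[il[a]])
    s6 <- (rmin^2 / d2[sel])^3
    e <- e + sum(epsij * (s6^2 - 2 * s6))
  }
  e
}

# Deterministic quasi-uniform unit sphere points (golden-spiral lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area from a fixed deterministic golden-spiral point
#' set on each probe-expanded atom sphere; a point buried inside any
#' neighbour's expanded sphere is inaccessible.
#'
#' @param atoms data.frame with x, y, z, radius (a `protein_structure`'s or
#'   `ligand_pose`'s `atoms`, or any atom table with radii assigned).
#' @param probe Probe radius, Angstrom.
#' @param n_sphere_points Points per atom sphere.
#' @return List with `per_atom` (A^2) and `total`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_sphere_points = 240) {
  if (!is.data.frame(atoms) && !is.null(atoms$atoms)) atoms <- atoms$atoms
  if (any(is.na(atoms$radius))) stop("assign radii before SASA")
  per <- sasa_cpp(as.matrix(atoms[, c("x", "y", "z")]), atoms$radius, probe,
                  .sphere_points(n_sphere_points))
  list(per_atom = as.numeric(per), total = sum(per))
}

#' Hydrophobic (buried-surface) energy
#'
#' Surface-tension model of the hydrophobic contribution:
#' `gamma * [SASA(complex) - SASA(protein) - SASA(ligand)]`. The bracket is
#' the (negative) buried area, so binding poses give a favourable (<= 0)
#' energy for positive gamma.
#'
#' @param protein `protein_structure` with radii.
#' @param ligand `ligand_pose` with radii.
#' @param gamma Surface tension coefficient, kJ/mol/A^2.
#' @param probe Probe radius, Angstrom.
#' @param n_sphere_points Points per atom sphere.
#' @return Energy in kJ/mol.
#' @export
hydrophobic_energy <- function(protein, ligand, gamma = 0.0226, probe = 1.4,
                               n_sphere_points = 240) {
  cols <- c("x", "y", "z", "radius")
  complex_atoms <- rbind(protein$atoms[, cols], ligand$atoms[, cols])
  s_complex <- shrake_rupley_sasa(complex_atoms, probe, n_sphere_points)$total
  s_prot <- shrake_rupley_sasa(protein$atoms[, cols], probe,
                               n_sphere_points)$total
  s_lig <- shrake_rupley_sasa(ligand$atoms[, cols], probe,
                              n_sphere_points)$total
  gamma * (s_complex - s_prot - s_lig)
}
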