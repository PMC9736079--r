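# Rotation-invariant 3-D shape descriptors: a star-shaped radial surface
# function sampled over the sphere, expanded in real spherical harmonics;
# per-degree coefficient energies c_l = sqrt(sum_m a_lm^2) are compared by
# Euclidean distance. Pocket shape is quantified via a probe-atom protomol
# filling the reference-ligand-occupied volume.

#' Spherical sampling directions with quadrature weights
#'
#' Gauss-Legendre nodes in cos(theta) crossed with a uniform azimuthal grid.
#' This product rule integrates spherical harmonics exactly up to high
#' degree, which makes the fitted per-degree energies rotation-invariant to
#' near machine precision for smooth radial functions.
#'
#' @param n_theta Number of polar nodes (Gauss-Legendre).
#' @param n_phi Number of azimuthal nodes (uniform).
#' @return List with `dirs` (n x 3 unit vectors) and `weights` (summing to
#'   4*pi).
#' @export
sphere_quadrature <- function(n_theta = 16, n_phi = 32) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  ct <- gl$x; wt <- gl$w
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  st <- sqrt(pmax(0, 1 - ct^2))
  dirs <- cbind(rep(st, each = n_phi) * cos(rep(phi, n_theta)),
                rep(st, each = n_phi) * sin(rep(phi, n_theta)),
                rep(ct, each = n_phi))
  w <- rep(wt, each = n_phi) * (2 * pi / n_phi)
  list(dirs = dirs, weights = w)
}

#' Star-shaped radial surface function
#'
#' For each direction, the largest distance from the centroid to any
#' atom-sphere surface along that ray (analytic ray-sphere intersection).
#' Directions along which no sphere is hit are an error: the surface must be
#' star-shaped around the centroid.
#'
#' @param atoms data.frame with x, y, z, radius.
#' @param centroid Length-3 centre of expansion.
#' @param directions n x 3 unit vectors.
#' @return Numeric vector of radial distances (> 0).
#' @export
radial_shape_function <- function(atoms, centroid, directions) {
  if (!is.data.frame(atoms) && !is.null(atoms$atoms)) atoms <- atoms$atoms
  if (nrow(atoms) == 0) stop("empty atom set")
  if (any(is.na(atoms$radius))) stop("assign radii first")
  C <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, centroid)  # n_atom x 3
  r2 <- atoms$radius^2
  cc <- rowSums(C^2)
  out <- numeric(nrow(directions))
  for (d in seq_len(nrow(directions))) {
    b <- C %*% directions[d, ]           # c . d per atom
    disc <- b^2 - cc + r2
    hit <- disc >= 0
    if (!any(hit)) stop("no surface along direction ", d,
                        "; shape not star-shaped about the centroid")
    t <- b[hit] + sqrt(disc[hit])        # far intersection
    out[d] <- max(t)
  }
  if (any(out <= 0)) stop("non-positive radial sample; centroid outside shape")
  out
}

# Real spherical harmonics basis matrix: rows = directions, cols = (l,m)
# for l = 0..lmax, m = -l..l. Orthonormal on the sphere.
.sh_basis <- function(dirs, lmax) {
  ct <- dirs[, 3]
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  B <- matrix(0, n, (lmax + 1)^2)
  col <- 0
  for (l in 0:lmax) {
    # pracma::legendre returns rows m = 0..l of P_l^m (Condon-Shortley)
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    for (m in (-l):l) {
      col <- col + 1
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                  factorial(l - am) / factorial(l + am))
      Pm <- P[am + 1, ]
      B[, col] <-
        if (m == 0) nrm * Pm
        else if (m > 0) sqrt(2) * nrm * Pm * cos(m * phi)
        else sqrt(2) * nrm * Pm * sin(am * phi)
    }
  }
  B
}

#' Spherical-harmonics expansion of a radial function
#'
#' Weighted least-squares fit of real spherical harmonics up to `l_max` to
#' radial samples; with quadrature weights this is the discrete projection.
#' Returns the rotation-invariant per-degree energies
#' `c_l = sqrt(sum_m a_lm^2)`.
#'
#' @param samples Radial values, one per direction.
#' @param directions n x 3 unit vectors.
#' @param l_max Maximum expansion degree.
#' @param weights Optional quadrature weights (defaults to equal weights).
#' @return `shape_descriptor`: list with `c_l` (length l_max+1), `l_max`,
#'   `coefficients` (full a_lm vector), `condition`.
#' @export
sh_expand <- function(samples, directions, l_max = 6, weights = NULL) {
  n <- length(samples)
  if (n < (l_max + 1)^2)
    stop("need at least (l_max+1)^2 = ", (l_max + 1)^2, " samples, got ", n)
  if (is.null(weights)) weights <- rep(4 * pi / n, n)
  B <- .sh_basis(directions, l_max)
  sw <- sqrt(weights)
  qrB <- qr(B * sw)
  kap <- 1 / .Machine$double.eps
  R <- qr.R(qrB)
  dg <- abs(diag(R))
  if (min(dg) > 0) kap <- max(dg) / min(dg)
  if (kap > 1e8)
    stop(sprintf("ill-conditioned harmonic fit (condition number %.3g); ",
                 kap), "use more/better-spread directions")
  a <- qr.coef(qrB, samples * sw)
  cl <- vapply(0:l_max, function(l) {
    ix <- (l^2 + 1):((l + 1)^2)
    sqrt(sum(a[ix]^2))
  }, 0)
  structure(list(c_l = cl, l_max = l_max, coefficients = a,
                 condition = kap), class = "shape_descriptor")
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat("shape_descriptor (l_max =", x$l_max, "): c_l =",
      paste(signif(x$c_l, 4), collapse = " "), "\n")
  invisible(x)
}

#' Shape descriptor of an atom set
#'
#' Convenience pipeline: centroid (unweighted mean of atom centres), radial
#' surface sampling on a quadrature grid, harmonic expansion.
#'
#' @param atoms data.frame with x, y, z, radius, or an object carrying
#'   `$atoms`.
#' @param l_max Maximum degree.
#' @param n_theta,n_phi Quadrature resolution.
#' @return `shape_descriptor` (with the centroid attached as attribute).
#' @export
shape_descriptor <- function(atoms, l_max = 6, n_theta = 16, n_phi = 32) {
  if (!is.data.frame(atoms) && !is.null(atoms$atoms)) atoms <- atoms$atoms
  quad <- sphere_quadrature(n_theta, n_phi)
  centroid <- colMeans(as.matrix(atoms[, c("x", "y", "z")]))
  r <- radial_shape_function(atoms, centroid, quad$dirs)
  d <- sh_expand(r, quad$dirs, l_max, quad$weights)
  attr(d, "centroid") <- centroid
  d
}

#' Euclidean distance between shape descriptors
#'
#' Distance between the per-degree energy vectors; smaller values mean more
#' similar shapes. Descriptors must share `l_max`.
#'
#' @param d1,d2 `shape_descriptor` objects.
#' @return Non-negative distance.
#' @export
shape_distance <- function(d1, d2) {
  if (d1$l_max != d2$l_max) stop("descriptors have different l_max")
  sqrt(sum((d1$c_l - d2$c_l)^2))
}

#' Generate a pocket protomol
#'
#' Fills the reference-ligand-occupied pocket with carbon probe atoms on a
#' cubic lattice: probes lie within `pocket_radius` of the reference
#' centroid, clash with no protein atom, and (when a protein is present) sit
#' within `reach` of some protein atom surface so bulk solvent is excluded.
#'
#' @param protein `protein_structure` with radii (may have zero atoms).
#' @param reference `ligand_pose` defining the pocket centre.
#' @param pocket_radius Sphere radius around the reference centroid,
#'   Angstrom.
#' @param grid_step Lattice step, Angstrom.
#' @param probe_radius Probe atom radius (carbon vdW).
#' @param reach Maximum surface distance from a probe centre to the nearest
#'   protein atom, Angstrom.
#' @return `protomol`: list with `atoms` (x, y, z, radius, element = "C")
#'   and the generating parameters. Errors if no probe survives.
#' @export
generate_protomol <- function(protein, reference, pocket_radius = 10,
                              grid_step = 0.8, probe_radius = 1.7,
                              reach = 5.0) {
  centroid <- colMeans(as.matrix(reference$atoms[, c("x", "y", "z")]))
  g <- seq(-pocket_radius, pocket_radius, by = grid_step)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g, KEEP.OUT.ATTRS = FALSE))
  pts <- sweep(pts, 2, -centroid)
  keep <- rowSums(sweep(pts, 2, centroid)^2) <= pocket_radius^2
  pts <- pts[keep, , drop = FALSE]
  pa <- protein$atoms
  if (nrow(pa) > 0) {
    if (any(is.na(pa$radius))) stop("assign protein radii first")
    ok <- rep(TRUE, nrow(pts))
    near <- rep(FALSE, nrow(pts))
    for (a in seq_len(nrow(pa))) {
      d2 <- (pts[, 1] - pa$x[a])^2 + (pts[, 2] - pa$y[a])^2 +
            (pts[, 3] - pa$z[a])^2
      ok <- ok & (d2 >= (pa$radius[a] + probe_radius)^2)
      near <- near | (d2 <= (pa$radius[a] + probe_radius + reach)^2)
    }
    pts <- pts[ok & near, , drop = FALSE]
  }
  if (nrow(pts) == 0) stop("empty protomol: no pocket volume found")
  structure(list(atoms = data.frame(element = "C", x = pts[, 1],
                                    y = pts[, 2], z = pts[, 3],
                                    radius = probe_radius),
                 centroid = centroid, pocket_radius = pocket_radius,
                 grid_step = grid_step, probe_radius = probe_radius),
            class = "protomol")
}

#' @export
print.protomol <- function(x, ...) {
  cat("protomol:", nrow(x$atoms), "probes, step", x$grid_step, "A\n")
  invisible(x)
}

#' Write a protomol as PDB
#'
#' @param pm A `protomol`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_protomol_pdb <- function(pm, path) {
  n <- nrow(pm$atoms)
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(pm$atoms[, c("x", "y",
                                                             "z")]))),
                   type = rep("HETATM", n), resno = rep(1L, n),
                   resid = rep("PRB", n), eleno = seq_len(n),
                   elety = rep("C", n), chain = rep("P", n),
                   elesy = rep("C", n), o = rep(1, n), b = rep(0, n))
  invisible(path)
}
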