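# Linearized Poisson-Boltzmann electrostatics of the ligand-free protein on
# a cubic finite-difference grid, and the site-interaction energy
# E = sum_j phi_j q_j over ligand atom positions.

#' Build a cubic grid around a protein
#'
#' Cube centred on the protein's geometric centre. The edge is chosen so the
#' protein's longest Cartesian extent occupies `fill_fraction` of the box
#' edge; the node count per axis is `edge/spacing` rounded up to the next odd
#' integer (odd counts put a node at the box centre).
#'
#' @param protein A `protein_structure`.
#' @param spacing Grid spacing, Angstrom per node.
#' @param fill_fraction Fraction of the box edge occupied by the longest
#'   protein extent (0 < fill < 1).
#' @param min_edge Minimum edge, Angstrom, protecting degenerate (single
#'   atom) extents.
#' @return `grid_spec`: list(origin, spacing, dims).
#' @export
build_grid <- function(protein, spacing = 0.6, fill_fraction = 0.70,
                       min_edge = 12) {
  if (nrow(protein$atoms) == 0) stop("empty protein")
  if (fill_fraction <= 0 || fill_fraction >= 1)
    stop("fill_fraction must be in (0,1)")
  xyz <- as.matrix(protein$atoms[, c("x", "y", "z")])
  extent <- max(apply(xyz, 2, function(v) diff(range(v))))
  edge <- max(extent / fill_fraction, min_edge)
  n <- as.integer(ceiling(edge / spacing))
  if (n %% 2L == 0L) n <- n + 1L
  centre <- colMeans(apply(xyz, 2, range))
  origin <- centre - (n - 1) / 2 * spacing
  structure(list(origin = unname(origin), spacing = spacing,
                 dims = c(n, n, n)), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d nodes, h = %.3f A, edge %.1f A\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              (x$dims[1] - 1) * x$spacing))
  invisible(x)
}

.grid_axes <- function(grid) {
  lapply(1:3, function(d)
    grid$origin[d] + (seq_len(grid$dims[d]) - 1) * grid$spacing)
}

# Debye screening parameter kappa (1/Angstrom) in the solvent from ionic
# strength (mol/L) for a 1:1 electrolyte: kappa^2 = 8 pi l_B n_ion.
.kappa_solvent <- function(ionic_strength, eps_out, temperature) {
  if (ionic_strength <= 0) return(0)
  lB <- .kcoul / (eps_out * .kB * temperature)
  n <- ionic_strength * 6.02214076e-4  # ions per A^3 per sign
  sqrt(8 * pi * lB * n)
}

#' Map dielectric, ion accessibility, and charge sources onto a grid
#'
#' Node/edge classification uses the van der Waals surface: a point inside
#' any atom sphere is solute (`eps_in`), otherwise solvent (`eps_out`).
#' Dielectric values live on grid edges (classified at edge midpoints). The
#' modified screening factor kappa^2 is zero at nodes within
#' `radius + ion_radius` of any atom (solute plus Stern layer) and takes the
#' solvent Debye value elsewhere. Protein charges are spread to the eight
#' surrounding nodes with trilinear weights, conserving total charge.
#'
#' @param protein `protein_structure` with radii and charges assigned.
#' @param grid `grid_spec`.
#' @param eps_in,eps_out Solute and solvent dielectric constants.
#' @param ionic_strength mol/L.
#' @param ion_radius Stern-layer (ion exclusion) radius, Angstrom.
#' @param probe Solvent probe radius, Angstrom (carried for the SASA module;
#'   the boundary here is the vdW surface).
#' @param temperature Kelvin.
#' @return `dielectric_map` holding edge dielectrics, per-node kappa^2 and
#'   source charge, plus the point-charge list.
#' @export
map_dielectric <- function(protein, grid, eps_in = 2, eps_out = 80,
                           ionic_strength = 0.145, ion_radius = 2.0,
                           probe = 1.4, temperature = 298.15) {
  at <- protein$atoms
  if (any(is.na(at$radius))) stop("assign radii before mapping")
  if (any(is.na(at$charge))) stop("assign charges before mapping")
  dims <- grid$dims; h <- grid$spacing
  ax <- .grid_axes(grid)
  kap <- .kappa_solvent(ionic_strength, eps_out, temperature)

  # edge midpoint coordinates per direction; classify against atom spheres
  inside_any <- function(px, py, pz, extra = 0) {
    # px,py,pz: equal-length coordinate vectors (flattened grid subsets)
    ins <- rep(FALSE, length(px))
    for (a in seq_len(nrow(at))) {
      r2 <- (at$radius[a] + extra)^2
      d2 <- (px - at$x[a])^2 + (py - at$y[a])^2 + (pz - at$z[a])^2
      ins <- ins | (d2 < r2)
      if (all(ins)) break
    }
    ins
  }
  edge_eps <- function(dir) {
    dd <- dims; dd[dir] <- dd[dir] - 1L
    mids <- ax
    mids[[dir]] <- mids[[dir]][-dims[dir]] + h / 2
    pts <- as.matrix(expand.grid(x = mids[[1]], y = mids[[2]],
                                 z = mids[[3]], KEEP.OUT.ATTRS = FALSE))
    e <- ifelse(inside_any(pts[, 1], pts[, 2], pts[, 3]), eps_in, eps_out)
    array(e, dd)
  }
  epsx <- edge_eps(1); epsy <- edge_eps(2); epsz <- edge_eps(3)

  nodes <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                 KEEP.OUT.ATTRS = FALSE))
  excluded <- inside_any(nodes[, 1], nodes[, 2], nodes[, 3],
                         extra = ion_radius)
  kappa2 <- array(ifelse(excluded, 0, kap^2), dims)

  if (!any(epsx == eps_in) && nrow(at) > 0 && any(at$radius > 0) &&
      h > 2 * max(at$radius))
    stop("grid too coarse: no solute edge captured (spacing ", h, " A)")

  # trilinear charge spreading
  src <- array(0, dims)
  for (a in seq_len(nrow(at))) {
    q <- at$charge[a]
    if (q == 0) next
    fi <- (at$x[a] - grid$origin[1]) / h
    fj <- (at$y[a] - grid$origin[2]) / h
    fk <- (at$z[a] - grid$origin[3]) / h
    i0 <- floor(fi); j0 <- floor(fj); k0 <- floor(fk)
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= dims[1] - 1 ||
        j0 >= dims[2] - 1 || k0 >= dims[3] - 1)
      stop("charge of atom ", a, " falls outside the grid")
    wx <- fi - i0; wy <- fj - j0; wz <- fk - k0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
           (if (dk) wz else 1 - wz)
      src[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] <-
        src[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] + w * q
    }
  }
  stopifnot(abs(sum(src) - sum(at$charge)) < 1e-6)

  structure(list(grid = grid, epsx = epsx, epsy = epsy, epsz = epsz,
                 kappa2 = kappa2, source = src,
                 charges = data.frame(x = at$x, y = at$y, z = at$z,
                                      q = at$charge),
                 eps_in = eps_in, eps_out = eps_out, kappa = kap,
                 temperature = temperature),
            class = "dielectric_map")
}

#' Uniform-dielectric map for point charges
#'
#' Convenience constructor for benchmark problems: a homogeneous medium of
#' dielectric `eps` with optional Debye screening and explicit point
#' charges. Used to validate the solver against the screened-Coulomb closed
#' form.
#'
#' @param grid `grid_spec`.
#' @param charges data.frame with x, y, z, q.
#' @param eps Uniform dielectric constant.
#' @param ionic_strength mol/L (screening everywhere).
#' @param temperature Kelvin.
#' @return `dielectric_map`.
#' @export
uniform_map <- function(grid, charges, eps = 80, ionic_strength = 0.145,
                        temperature = 298.15) {
  dims <- grid$dims; h <- grid$spacing
  kap <- .kappa_solvent(ionic_strength, eps, temperature)
  src <- array(0, dims)
  for (a in seq_len(nrow(charges))) {
    fi <- (charges$x[a] - grid$origin[1]) / h
    fj <- (charges$y[a] - grid$origin[2]) / h
    fk <- (charges$z[a] - grid$origin[3]) / h
    i0 <- floor(fi); j0 <- floor(fj); k0 <- floor(fk)
    wx <- fi - i0; wy <- fj - j0; wz <- fk - k0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy) *
           (if (dk) wz else 1 - wz)
      src[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] <-
        src[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] + w * charges$q[a]
    }
  }
  structure(list(grid = grid,
                 epsx = array(eps, dims - c(1, 0, 0)),
                 epsy = array(eps, dims - c(0, 1, 0)),
                 epsz = array(eps, dims - c(0, 0, 1)),
                 kappa2 = array(kap^2, dims), source = src,
                 charges = charges, eps_in = eps, eps_out = eps,
                 kappa = kap, temperature = temperature),
            class = "dielectric_map")
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Finite-difference solution of `div(eps grad phi) - eps_out kappa^2 phi =
#' -4 pi k_c rho` by red-black Gauss-Seidel successive over-relaxation, with
#' Dirichlet boundary values from the analytic screened-Coulomb sum over the
#' source charges. Two source treatments are available:
#'
#' * `"regularized"` (default): the potential is split into the analytic
#'   Coulomb field of the charges in the reference dielectric plus a smooth
#'   numerical correction. This removes the lattice near-field error of
#'   point sources and is markedly more accurate close to charges. Requires
#'   all charges to sit in the reference (solute) dielectric; falls back to
#'   `"direct"` with a warning otherwise.
#' * `"direct"`: charges spread trilinearly onto grid nodes.
#'
#' @param map A `dielectric_map`.
#' @param method `"regularized"` or `"direct"`.
#' @param omega SOR relaxation factor.
#' @param tol Relative convergence tolerance on the per-sweep update.
#' @param maxit Maximum sweeps; non-convergence is an error carrying the
#'   residual history.
#' @return `potential_grid`: the grid spec plus `phi` (array, units kT/e)
#'   and solver diagnostics.
#' @export
solve_lpbe <- function(map, method = c("regularized", "direct"),
                       omega = 1.6, tol = 1e-6, maxit = 10000) {
  method <- match.arg(method)
  grid <- map$grid; dims <- grid$dims; h <- grid$spacing
  kT <- .kB * map$temperature
  pref <- .kcoul / kT  # converts q/(eps*r) sums to kT/e
  lambda <- map$eps_out * map$kappa2  # modified screening factor

  ch <- map$charges[map$charges$q != 0, , drop = FALSE]
  n_nodes <- prod(dims)
  boundary <- array(FALSE, dims)
  boundary[c(1, dims[1]), , ] <- TRUE
  boundary[, c(1, dims[2]), ] <- TRUE
  boundary[, , c(1, dims[3])] <- TRUE

  # Dirichlet values: screened Coulomb in the solvent dielectric
  u0 <- array(0, dims)
  if (nrow(ch)) {
    bc <- coulomb_grid_cpp(dims, grid$origin, h,
                           as.matrix(ch[, c("x", "y", "z")]), ch$q,
                           map$eps_out, map$kappa, pref, 1e-9,
                           pref * .cube_inv_r / (map$eps_out * h))
    u0[boundary] <- array(bc, dims)[boundary]
  }

  if (method == "regularized" && nrow(ch)) {
    # reference dielectric at charge locations must be homogeneous
    eps_ref <- map$eps_in
    ax <- .grid_axes(grid)
    near_i <- pmin(pmax(round((ch$x - grid$origin[1]) / h), 0), dims[1] - 1) + 1
    near_j <- pmin(pmax(round((ch$y - grid$origin[2]) / h), 0), dims[2] - 1) + 1
    near_k <- pmin(pmax(round((ch$z - grid$origin[3]) / h), 0), dims[3] - 1) + 1
    # sample the x-edge dielectric adjacent to each charge's nearest node
    ei <- pmin(near_i, dims[1] - 1)
    in_ref <- vapply(seq_len(nrow(ch)), function(c)
      map$epsx[ei[c], near_j[c], near_k[c]] == eps_ref, TRUE)
    if (!all(in_ref)) {
      warning("charges outside the reference dielectric; using direct ",
              "source treatment")
      method <- "direct"
    }
  }

  if (method == "regularized" && nrow(ch)) {
    eps_ref <- map$eps_in
    g <- coulomb_grid_cpp(dims, grid$origin, h,
                          as.matrix(ch[, c("x", "y", "z")]), ch$q,
                          eps_ref, 0, pref, h * 1e-6,
                          pref * .cube_inv_r / (eps_ref * h))
    g <- array(g, dims)
    # src for the correction v: -h^2 * Lambda * g + sum_edges (eps_e -
    # eps_ref)(g_nb - g_0); the interface term is nonzero only on
    # solvent-crossing edges.
    src <- -h^2 * lambda * g
    add_dir <- function(src, eps_edge, dir) {
      dd <- dim(eps_edge)
      de <- eps_edge - eps_ref
      idx_lo <- lapply(dims, seq_len)
      idx_hi <- idx_lo
      idx_lo[[dir]] <- seq_len(dims[dir] - 1L)       # node n
      idx_hi[[dir]] <- seq_len(dims[dir] - 1L) + 1L  # node n+1
      g_lo <- do.call(`[`, c(list(g), idx_lo))
      g_hi <- do.call(`[`, c(list(g), idx_hi))
      contrib <- de * (g_hi - g_lo)
      # to node n: +(eps-eps_ref)(g_hi-g_lo); to node n+1: -(...)
      s_lo <- do.call(`[`, c(list(src), idx_lo)) + contrib
      s_hi <- do.call(`[`, c(list(src), idx_hi)) - contrib
      src <- do.call(`[<-`, c(list(src), idx_lo, list(s_lo)))
      do.call(`[<-`, c(list(src), idx_hi, list(s_hi)))
    }
    src <- add_dir(src, map$epsx, 1)
    src <- add_dir(src, map$epsy, 2)
    src <- add_dir(src, map$epsz, 3)
    v0 <- u0 - g
    v0[!boundary] <- 0
    src[boundary] <- 0
    sol <- sor_lpbe_cpp(dims, h, as.numeric(map$epsx), as.numeric(map$epsy),
                        as.numeric(map$epsz), as.numeric(lambda),
                        as.numeric(src), as.numeric(v0), omega, tol, maxit)
    phi <- array(sol$u, dims) + g
  } else {
    src <- 4 * pi * pref * map$source / h
    src[boundary] <- 0
    sol <- sor_lpbe_cpp(dims, h, as.numeric(map$epsx), as.numeric(map$epsy),
                        as.numeric(map$epsz), as.numeric(lambda),
                        as.numeric(src), as.numeric(u0), omega, tol, maxit)
    phi <- array(sol$u, dims)
  }
  if (!sol$converged)
    stop("LPBE solver did not converge in ", maxit, " sweeps; residual ",
         "history tail: ",
         paste(signif(utils::tail(sol$residual_history, 5), 4),
               collapse = " "))
  structure(list(grid = grid, phi = phi, units = "kT/e",
                 temperature = map$temperature, method = method,
                 iterations = sol$iterations,
                 final_residual = utils::tail(sol$residual_history, 1),
                 grid_id = sprintf("%dx%dx%d@%.3f/%s", dims[1], dims[2],
                                   dims[3], h, method)),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf(
    "potential_grid %s: phi in %s, range [%.3g, %.3g], %d sweeps\n",
    x$grid_id, x$units, min(x$phi), max(x$phi), x$iterations))
  invisible(x)
}

#' Interpolate the electrostatic potential at ligand sites
#'
#' Trilinear interpolation of the node potential, exact at nodes. Sites must
#' be strictly inside the grid; an outside site is an error naming the atom
#' index (extrapolation is not performed).
#'
#' @param pot A `potential_grid`.
#' @param sites Numeric matrix (n x 3) of coordinates, Angstrom.
#' @return Potential values in kcal/(mol e).
#' @export
interpolate_esp <- function(pot, sites) {
  sites <- matrix(as.numeric(sites), ncol = 3)
  grid <- pot$grid; h <- grid$spacing; dims <- grid$dims
  kT <- .kB * pot$temperature
  out <- numeric(nrow(sites))
  for (s in seq_len(nrow(sites))) {
    f <- (sites[s, ] - grid$origin) / h
    i0 <- floor(f)
    if (any(f < 0) || any(i0 > dims - 2 & f > i0))
      stop("site ", s, " lies outside the potential grid")
    i0 <- pmin(i0, dims - 2)
    w <- f - i0
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      wt <- (if (di) w[1] else 1 - w[1]) * (if (dj) w[2] else 1 - w[2]) *
            (if (dk) w[3] else 1 - w[3])
      acc <- acc + wt * pot$phi[i0[1] + di + 1, i0[2] + dj + 1,
                                i0[3] + dk + 1]
    }
    out[s] <- acc * kT  # kT/e -> kcal/(mol e)
  }
  out
}

#' Electrostatic interaction energy at ligand sites
#'
#' The sum over ligand atoms of site potential times partial charge,
#' `E = sum_j phi_j q_j`, in kcal/mol: the energy of assembling the ligand
#' charge distribution in the field of the ligand-free protein.
#'
#' @param phi Site potentials, kcal/(mol e).
#' @param q Site partial charges, e.
#' @return Energy in kcal/mol.
#' @export
electrostatic_interaction_energy <- function(phi, q) {
  if (length(phi) != length(q)) stop("phi and q length mismatch")
  sum(phi * q)
}
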