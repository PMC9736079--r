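# Shared in-code fixtures: tiny structures built programmatically.

# Minimal protein-like object from raw atom fields (bypasses file IO).
make_protein <- function(x, y, z, element = "C", charge = 0,
                         radius = NA_real_, atom_name = element,
                         resid = "GLY", resno = seq_along(x), chain = "A",
                         is_metal = FALSE) {
  n <- length(x)
  for (v in c("element", "charge", "radius", "atom_name", "resid", "resno",
              "chain", "is_metal"))
    assign(v, rep_len(get(v), n))
  structure(list(atoms = data.frame(
    element = element, x = x, y = y, z = z, radius = radius,
    charge = charge, atom_name = atom_name, resid = resid, resno = resno,
    chain = chain, is_metal = is_metal, stringsAsFactors = FALSE),
    source = "in-memory"), class = "protein_structure")
}

make_pose <- function(x, y, z, element = "C", charge = NA_real_,
                      bonds = NULL, name = "pose", formal_charge = 0L,
                      radius = NA_real_) {
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  structure(list(name = name,
                 atoms = data.frame(element = element, x = x, y = y, z = z,
                                    radius = radius, charge = charge,
                                    stringsAsFactors = FALSE),
                 bonds = bonds, formal_charge = formal_charge),
            class = "ligand_pose")
}

# 5-atom toy PDB: 3 protein atoms (one H), 1 water, 1 zinc.
write_toy_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   GLY A   1      -0.500   0.870   0.000  1.00  0.00           H",
    "HETATM    4  O   HOH A   2       5.000   5.000   5.000  1.00  0.00           O",
    "HETATM    5 ZN    ZN A   3       3.000   3.000   3.000  1.00  0.00          ZN",
    "END")
  writeLines(lines, path)
  path
}

# benzene as MOL2 (12 atoms, 12 bonds)
write_benzene_mol2 <- function(path) {
  ang <- (0:5) * pi / 3
  cx <- 1.39 * cos(ang); cy <- 1.39 * sin(ang)
  hx <- 2.49 * cos(ang); hy <- 2.49 * sin(ang)
  lines <- c("@<TRIPOS>MOLECULE", "benzene", " 12 12 1", "SMALL",
             "NO_CHARGES", "", "@<TRIPOS>ATOM")
  for (i in 1:6)
    lines <- c(lines, sprintf("%4d C%d %9.4f %9.4f %9.4f C.ar 1 BNZ 0.0000",
                              i, i, cx[i], cy[i], 0))
  for (i in 1:6)
    lines <- c(lines, sprintf("%4d H%d %9.4f %9.4f %9.4f H 1 BNZ 0.0000",
                              i + 6, i, hx[i], hy[i], 0))
  lines <- c(lines, "@<TRIPOS>BOND")
  b <- 0
  for (i in 1:6) {
    b <- b + 1
    lines <- c(lines, sprintf("%4d %4d %4d ar", b, i, i %% 6 + 1))
  }
  for (i in 1:6) {
    b <- b + 1
    lines <- c(lines, sprintf("%4d %4d %4d 1", b, i, i + 6))
  }
  writeLines(lines, path)
  path
}

# ideal tetrahedral methane with C-H length 1.09
make_methane <- function() {
  s <- 1.09 / sqrt(3)
  make_pose(x = c(0, s, -s, s, -s), y = c(0, s, -s, -s, s),
            z = c(0, s, s, -s, -s), element = c("C", "H", "H", "H", "H"),
            bonds = data.frame(i = 1L, j = 2:5, order = 1L),
            name = "methane")
}

make_water <- function() {
  make_pose(x = c(0, 0.9572, -0.2399), y = c(0, 0, 0.9272), z = c(0, 0, 0),
            element = c("O", "H", "H"),
            bonds = data.frame(i = c(1L, 1L), j = c(2L, 3L), order = 1L),
            name = "water")
}

# 3-D rotation matrix from axis-angle
rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

rotate_atoms <- function(atoms, R) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# small uniform point-charge benchmark solved on a cube of given spacing
dh_benchmark <- function(spacing, edge = 16.2, eps = 80, I = 0.145, q = 1) {
  n <- as.integer(ceiling(edge / spacing))
  if (n %% 2 == 0) n <- n + 1L
  grid <- structure(list(origin = rep(-(n - 1) / 2 * spacing, 3),
                         spacing = spacing, dims = c(n, n, n)),
                    class = "grid_spec")
  map <- uniform_map(grid, data.frame(x = 0, y = 0, z = 0, q = q),
                     eps = eps, ionic_strength = I)
  pot <- solve_lpbe(map)
  list(grid = grid, pot = pot, eps = eps, I = I, q = q)
}

# analytic screened Coulomb in kcal/(mol e) at 298.15 K
dh_analytic <- function(r, eps = 80, I = 0.145, q = 1) {
  kc <- 332.0637133
  kT <- 0.0019872041 * 298.15
  lB <- kc / (eps * kT)
  kap <- if (I > 0) sqrt(8 * pi * lB * I * 6.02214076e-4) else 0
  kc * q * exp(-kap * r) / (eps * r)
}

# max relative error of the solved potential against the closed form over
# grid nodes with radius in [rmin, rmax]
dh_max_rel_err <- function(bench, rmin = 1.8, rmax = NULL) {
  grid <- bench$grid
  n <- grid$dims[1]; h <- grid$spacing
  if (is.null(rmax)) rmax <- (n - 1) * h / 2
  ax <- grid$origin[1] + (seq_len(n) - 1) * h
  nodes <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r <- sqrt(rowSums(nodes^2))
  sel <- r >= rmin & r <= rmax
  phi <- interpolate_esp(bench$pot, nodes[sel, , drop = FALSE])
  ana <- dh_analytic(r[sel], bench$eps, bench$I, bench$q)
  max(abs(phi - ana) / abs(ana))
}
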