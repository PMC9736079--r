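# Ligand-centric descriptors, per-descriptor similarity to the reference,
# and atom-pair fingerprint (Tanimoto) similarity.

.element_props <- function() {
  read.delim(.extdata("element_props.tsv"), stringsAsFactors = FALSE)
}

# vdW volume by lattice occupancy of the atom spheres
.vdw_volume <- function(atoms, step = 0.4) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atoms$radius
  lo <- apply(xyz - r, 2, min) - step
  hi <- apply(xyz + r, 2, max) + step
  gx <- seq(lo[1], hi[1], by = step)
  gy <- seq(lo[2], hi[2], by = step)
  gz <- seq(lo[3], hi[3], by = step)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                               KEEP.OUT.ATTRS = FALSE))
  occ <- rep(FALSE, nrow(pts))
  for (a in seq_len(nrow(atoms))) {
    occ <- occ | ((pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
                  (pts[, 3] - xyz[a, 3])^2 <= r[a]^2)
  }
  sum(occ) * step^3
}

# H-bond donor/acceptor counts by simple element rules: donors = H atoms
# bonded to N or O; acceptors = N and O atoms, excluding quaternary
# (4-heavy-neighbour) nitrogens.
.hb_counts <- function(ligand) {
  el <- ligand$atoms$element
  bonds <- ligand$bonds
  nbrs <- function(a) c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])
  hbd <- 0L
  for (a in which(el %in% c("N", "O")))
    hbd <- hbd + sum(el[nbrs(a)] == "H")
  hba <- 0L
  for (a in which(el %in% c("N", "O"))) {
    heavy <- sum(el[nbrs(a)] != "H")
    if (el[a] == "N" && heavy >= 4) next
    hba <- hba + 1L
  }
  c(hbd = hbd, hba = hba)
}

#' Ligand-centric descriptor vector
#'
#' The eight descriptors combined into the similarity block of the ranking:
#' hydrogen-bond acceptor and donor counts (element rules), dipole moment
#' (Debye, from partial charges about the centroid), electron affinity and
#' ionization potential (classically uncomputable; element-table proxies,
#' flagged), globularity (area of the equal-volume sphere / SASA, in (0,1]),
#' solvent-accessible surface area (A^2), and van der Waals volume (A^3).
#'
#' @param ligand `ligand_pose` with radii and charges assigned.
#' @param probe SASA probe radius.
#' @param volume_step Lattice step for the volume integral.
#' @param ea_ip_provider Optional function(ligand) returning
#'   `c(ea = , ip = )` in eV, replacing the element-mean proxies.
#' @return Named list of class `descriptor_vector` with fields hba, hbd,
#'   dipole, electron_affinity, globularity, ionization_potential, sasa,
#'   volume, and a logical `proxy_ea_ip` marker.
#' @export
compute_descriptors <- function(ligand, probe = 1.4, volume_step = 0.4,
                                ea_ip_provider = NULL) {
  at <- ligand$atoms
  if (any(is.na(at$radius))) stop("assign radii before descriptors")
  if (any(is.na(at$charge)))
    stop("assign partial charges (gasteiger_charges) before descriptors: ",
         "the dipole needs them")
  hb <- .hb_counts(ligand)
  centroid <- colMeans(as.matrix(at[, c("x", "y", "z")]))
  dip_vec <- colSums(at$charge *
                     sweep(as.matrix(at[, c("x", "y", "z")]), 2, centroid))
  dipole <- sqrt(sum(dip_vec^2)) * .e2debye
  sasa <- shrake_rupley_sasa(at, probe = probe)$total
  vol <- .vdw_volume(at, step = volume_step)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  glob <- min(1, 4 * pi * (r_eq + probe)^2 / sasa)
  if (is.null(ea_ip_provider)) {
    props <- .element_props()
    ix <- match(at$element, props$element)
    if (any(is.na(ix)))
      stop("no element properties for: ",
           paste(unique(at$element[is.na(ix)]), collapse = ", "))
    ea <- mean(props$ea_ev[ix]); ip <- mean(props$ip_ev[ix])
    proxy <- TRUE
  } else {
    v <- ea_ip_provider(ligand); ea <- v[["ea"]]; ip <- v[["ip"]]
    proxy <- FALSE
  }
  structure(list(hba = unname(hb["hba"]), hbd = unname(hb["hbd"]),
                 dipole = dipole, electron_affinity = ea,
                 globularity = glob, ionization_potential = ip,
                 sasa = sasa, volume = vol, proxy_ea_ip = proxy),
            class = "descriptor_vector")
}

.descriptor_names <- c("hba", "hbd", "dipole", "electron_affinity",
                       "globularity", "ionization_potential", "sasa",
                       "volume")

#' Per-descriptor similarity to the reference
#'
#' Scalar similarity on the unit range for each of the eight descriptors:
#' `min(|a|,|b|) / max(|a|,|b|)`, with opposite signs scoring 0 and the
#' degenerate both-zero case scoring 1. Symmetric, 1 iff equal.
#'
#' @param ref,query `descriptor_vector` objects.
#' @return Named numeric vector of 8 similarities in [0,1].
#' @export
descriptor_similarity <- function(ref, query) {
  vapply(.descriptor_names, function(nm) {
    a <- ref[[nm]]; b <- query[[nm]]
    if (a == 0 && b == 0) return(1)
    if (sign(a) * sign(b) < 0) return(0)
    min(abs(a), abs(b)) / max(abs(a), abs(b))
  }, 0)
}

#' Atom-pair fingerprint
#'
#' Counted features (type_i, type_j, topological distance) over all pairs of
#' heavy atoms, with atom type = (element, heavy-neighbour count, pi flag).
#' Distances are shortest bond-graph paths; for disconnected poses pairs are
#' counted within fragments only (with a warning).
#'
#' @param ligand `ligand_pose` with bond graph.
#' @param counted Keep feature counts (default); `FALSE` clamps every
#'   feature to presence/absence.
#' @return `atom_pair_fingerprint`: named integer vector of feature counts.
#' @export
atom_pair_fingerprint <- function(ligand, counted = TRUE) {
  el <- ligand$atoms$element
  heavy <- which(el != "H")
  if (length(heavy) < 2)
    return(structure(integer(0), class = "atom_pair_fingerprint"))
  bonds <- ligand$bonds
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(ligand$atoms) -
                                     igraph::vcount(g)))
  D <- igraph::distances(g, v = heavy, to = heavy)
  ords <- lapply(seq_along(el), function(a)
    c(bonds$order[bonds$i == a], bonds$order[bonds$j == a]))
  heavy_deg <- vapply(heavy, function(a)
    sum(el[c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])] != "H"), 0L)
  pi_flag <- vapply(heavy, function(a) any(ords[[a]] > 1), TRUE)
  atype <- sprintf("%s%d%s", el[heavy], heavy_deg,
                   ifelse(pi_flag, "p", ""))
  feats <- character(0)
  for (a in seq_along(heavy)) {
    for (b in seq_along(heavy)) {
      if (b <= a) next
      d <- D[a, b]
      if (!is.finite(d)) next
      tp <- sort(c(atype[a], atype[b]))
      feats <- c(feats, paste(tp[1], tp[2], d, sep = "|"))
    }
  }
  if (any(!is.finite(D[upper.tri(D)])))
    warning("disconnected pose ", ligand$name,
            ": atom pairs counted within fragments only")
  fp <- table(feats)
  counts <- as.integer(fp)
  if (!counted) counts <- pmin(counts, 1L)
  structure(setNames(counts, names(fp)), class = "atom_pair_fingerprint")
}

#' Molecular weight of a pose
#'
#' Sum of standard atomic masses (g/mol); used by the optional
#' molecular-weight library filter.
#'
#' @param ligand `ligand_pose`.
#' @return Molecular weight, g/mol.
#' @export
molecular_weight <- function(ligand) {
  masses <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
              F = 18.998, Na = 22.99, Mg = 24.305, Si = 28.085, P = 30.974,
              S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845,
              Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.904)
  m <- masses[ligand$atoms$element]
  if (any(is.na(m)))
    stop("no atomic mass for element(s): ",
         paste(unique(ligand$atoms$element[is.na(m)]), collapse = ", "))
  sum(m)
}

#' Tanimoto similarity of counted fingerprints
#'
#' Count-Tanimoto `sum(min) / sum(max)` over the union of features. Two
#' empty fingerprints score 1 with a warning.
#'
#' @param a,b `atom_pair_fingerprint` vectors.
#' @return Similarity in [0,1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) {
    warning("both fingerprints empty; Tanimoto defined as 1")
    return(1)
  }
  feats <- union(names(a), names(b))
  av <- setNames(rep(0L, length(feats)), feats)
  bv <- av
  av[names(a)] <- as.integer(a)
  bv[names(b)] <- as.integer(b)
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}
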