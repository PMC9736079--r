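# Readers/writers for protein structures (PDB) and ligand poses
# (SDF / MOL2 / PDB), plus the heteroatom-stripping rule applied to proteins.

# Standard residue names treated as protein; everything else is a
# heteroatom (water, cofactor, ligand) unless it is a metal kept on request.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL", "HID", "HIE", "HIP", "CYX",
          "ASH", "GLH", "LYN")

.metal_elements <- c("Li", "Na", "K", "Mg", "Ca", "Mn", "Fe", "Co", "Ni",
                     "Cu", "Zn", "Cd", "Hg")

#' Read a prepared protein structure from PDB
#'
#' Parses a PDB file and applies the heteroatom-stripping rule: all
#' non-protein atoms (waters, cofactors, ligands) are removed, optionally
#' keeping metal ions. Inputs are expected to be prepared structures
#' (hydrogens added, protonation fixed); a missing-hydrogen input triggers a
#' warning, not an error. For atoms with alternate locations the highest
#' occupancy altloc is retained.
#'
#' @param path PDB file.
#' @param keep_metals Keep metal heteroatoms (`TRUE`, default) or strip them.
#' @param metal_residues Optional character vector restricting which metal
#'   residue names are kept (e.g. `c("ZN")`); `NULL` keeps all metals.
#' @return A `protein_structure`: list with `atoms` data frame (element, x,
#'   y, z, radius, charge, atom_name, resid, resno, chain, is_metal).
#' @export
read_protein <- function(path, keep_metals = TRUE, metal_residues = NULL) {
  if (!file.exists(path)) stop("cannot read protein file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in ", path)
  # resolve altlocs: keep highest occupancy per (chain, resno, atom name)
  if (any(nzchar(trimws(at$alt)))) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      if (length(ix) == 1) return(ix)
      ix[which.max(at$o[ix])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  el <- .norm_element(ifelse(nzchar(trimws(at$elesy)), at$elesy,
                             substr(trimws(at$elety), 1, 1)))
  is_protein <- at$resid %in% .aa3
  is_metal <- !is_protein & el %in% .metal_elements
  if (!is.null(metal_residues))
    is_metal <- is_metal & at$resid %in% metal_residues
  keep <- is_protein | (keep_metals & is_metal)
  if (!any(is_protein)) stop("no protein atoms remain after stripping: ", path)
  at <- at[keep, , drop = FALSE]
  el <- el[keep]
  if (!any(el == "H"))
    warning("protein has no hydrogens; inputs are expected to be prepared ",
            "structures with explicit hydrogens")
  atoms <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                      radius = NA_real_, charge = NA_real_,
                      atom_name = trimws(at$elety), resid = at$resid,
                      resno = at$resno, chain = at$chain,
                      is_metal = (!at$resid %in% .aa3),
                      stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms, source = path), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s),",
      sum(x$atoms$is_metal), "metal(s)\n")
  invisible(x)
}

.new_ligand_pose <- function(name, atoms, bonds, formal_charge = 0L) {
  structure(list(name = name, atoms = atoms, bonds = bonds,
                 formal_charge = formal_charge), class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("ligand_pose '", x$name, "': ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, formal charge ", x$formal_charge, "\n", sep = "")
  invisible(x)
}

# Parse "M  CHG" style formal charges and optional PARTIAL_CHARGES data
# field out of one SDF record held as ChemmineR SDF object.
.pose_from_sdf <- function(sdf, id, fallback_name) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (nrow(ab) == 0) stop("SDF record with no atoms: ", fallback_name)
  el <- .norm_element(sub("_.*$", "", rownames(ab)))
  atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      radius = NA_real_, charge = NA_real_,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
  bonds <- if (nrow(bb))
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  else data.frame(i = integer(), j = integer(), order = integer())
  name <- ChemmineR::header(sdf)[["Molecule_Name"]]
  if (is.null(name) || !nzchar(name)) name <- fallback_name
  db <- ChemmineR::datablock(sdf)
  fc <- 0L
  if ("FORMAL_CHARGE" %in% names(db)) fc <- as.integer(db[["FORMAL_CHARGE"]])
  pose <- .new_ligand_pose(name, atoms, bonds, fc)
  if ("PARTIAL_CHARGES" %in% names(db)) {
    q <- as.numeric(strsplit(trimws(db[["PARTIAL_CHARGES"]]), "\\s+")[[1]])
    if (length(q) != nrow(atoms))
      stop("PARTIAL_CHARGES length mismatch in record ", name)
    pose$atoms$charge <- q
  }
  pose
}

.read_mol2 <- function(path) {
  lines <- readLines(path)
  recs <- which(grepl("^@<TRIPOS>MOLECULE", lines))
  if (!length(recs)) stop("no MOLECULE records in ", path)
  bounds <- c(recs, length(lines) + 1L)
  lapply(seq_along(recs), function(r) {
    blk <- lines[bounds[r]:(bounds[r + 1] - 1L)]
    name <- trimws(blk[2])
    a0 <- which(grepl("^@<TRIPOS>ATOM", blk))
    b0 <- which(grepl("^@<TRIPOS>BOND", blk))
    sect_end <- function(start) {
      nxt <- which(grepl("^@<TRIPOS>", blk) & seq_along(blk) > start)
      if (length(nxt)) min(nxt) - 1L else length(blk)
    }
    if (!length(a0)) stop("MOL2 record without ATOM section: ", name)
    arec <- blk[(a0 + 1L):sect_end(a0)]
    arec <- arec[nzchar(trimws(arec))]
    af <- strsplit(trimws(arec), "\\s+")
    atoms <- data.frame(
      element = .norm_element(vapply(af, function(f) sub("\\..*$", "", f[6]),
                                     "")),
      x = vapply(af, function(f) as.numeric(f[3]), 0),
      y = vapply(af, function(f) as.numeric(f[4]), 0),
      z = vapply(af, function(f) as.numeric(f[5]), 0),
      radius = NA_real_,
      charge = vapply(af, function(f)
        if (length(f) >= 9) as.numeric(f[9]) else NA_real_, 0),
      stringsAsFactors = FALSE)
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
    if (length(b0)) {
      brec <- blk[(b0 + 1L):sect_end(b0)]
      brec <- brec[nzchar(trimws(brec))]
      bf <- strsplit(trimws(brec), "\\s+")
      ord <- vapply(bf, function(f) f[4], "")
      ord <- ifelse(ord == "ar", "1.5", ifelse(ord == "am", "1", ord))
      bonds <- data.frame(i = vapply(bf, function(f) as.integer(f[2]), 0L),
                          j = vapply(bf, function(f) as.integer(f[3]), 0L),
                          order = as.numeric(ord))
    }
    if (all(is.na(atoms$charge))) atoms$charge <- NA_real_
    .new_ligand_pose(name, atoms, bonds)
  })
}

.read_ligand_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in ", path)
  el <- .norm_element(ifelse(nzchar(trimws(at$elesy)), at$elesy,
                             substr(trimws(at$elety), 1, 1)))
  atoms <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                      radius = NA_real_, charge = NA_real_,
                      stringsAsFactors = FALSE)
  nm <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  list(.new_ligand_pose(nm, atoms,
                        data.frame(i = integer(), j = integer(),
                                   order = integer())))
}

#' Read ligand poses
#'
#' Reads pre-placed ligand poses (already in the protein coordinate frame)
#' from SDF, MOL2, or PDB. One `ligand_pose` per record, in file order, with
#' record names preserved. SDF data fields `PARTIAL_CHARGES`
#' (whitespace-separated per-atom charges) and `FORMAL_CHARGE` are honoured
#' when present; MOL2 per-atom charges are read from column 9.
#'
#' @param path SDF/MOL2/PDB file; format chosen by extension.
#' @return List of `ligand_pose` objects.
#' @export
read_ligand_poses <- function(path) {
  if (!file.exists(path)) stop("cannot read ligand file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  poses <- switch(ext,
    sdf = ,
    sd = {
      sset <- ChemmineR::read.SDFset(path)
      ids <- ChemmineR::sdfid(sset)
      lapply(seq_along(sset), function(i)
        .pose_from_sdf(sset[[i]], i, ids[i]))
    },
    mol2 = .read_mol2(path),
    pdb = .read_ligand_pdb(path),
    stop("unsupported ligand format: .", ext))
  if (!length(poses)) stop("empty ligand file: ", path)
  for (p in poses) {
    if (nrow(p$atoms) == 0) stop("pose without atoms: ", p$name)
    xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
    if (any(!is.finite(xyz))) stop("non-finite coordinates in pose ", p$name)
    if (nrow(p$atoms) > 1 && all(abs(xyz[, 3]) < 1e-12) &&
        all(abs(xyz[, 2]) < 1e-12))
      warning("pose ", p$name, " looks 2-D (all y,z ~ 0)")
  }
  poses
}

#' Write ligand poses to SDF
#'
#' Emits V2000 SDF records with `PARTIAL_CHARGES` / `FORMAL_CHARGE` data
#' fields so that charge-bearing poses round-trip through
#' [read_ligand_poses()].
#'
#' @param poses List of `ligand_pose` objects (or a single pose).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ligand_poses <- function(poses, path) {
  if (inherits(poses, "ligand_pose")) poses <- list(poses)
  sdfs <- lapply(poses, function(p) {
    na <- nrow(p$atoms)
    nb <- nrow(p$bonds)
    ab <- cbind(p$atoms$x, p$atoms$y, p$atoms$z,
                matrix(0, na, 13))
    colnames(ab) <- paste0("C", 1:16)
    rownames(ab) <- paste(p$atoms$element, seq_len(na), sep = "_")
    bb <- if (nb) cbind(p$bonds$i, p$bonds$j, round(p$bonds$order),
                        matrix(0, nb, 4))
          else matrix(0, 0, 7)
    colnames(bb) <- paste0("C", 1:7)
    if (nb) rownames(bb) <- as.character(seq_len(nb))
    db <- c(FORMAL_CHARGE = as.character(p$formal_charge))
    if (!all(is.na(p$atoms$charge)))
      db <- c(db, PARTIAL_CHARGES = paste(sprintf("%.6f", p$atoms$charge),
                                          collapse = " "))
    methods::new(methods::getClassDef("SDF", package = "ChemmineR"),
        header = c(Molecule_Name = p$name, Source = "elscreen",
                   Comment = "",
                   Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                         na, nb)),
        atomblock = ab, bondblock = bb, datablock = db)
  })
  sset <- methods::new(methods::getClassDef("SDFset", package = "ChemmineR"),
                       SDF = sdfs, ID = vapply(poses, `[[`, "", "name"))
  ChemmineR::write.SDF(sset, path)
  invisible(path)
}

#' Structure manifest
#'
#' Summarizes a protein structure and a set of poses as a JSON-ready list
#' (atom counts per chain, metals, pose names and sizes); written alongside
#' screen outputs for provenance.
#'
#' @param protein A `protein_structure`.
#' @param poses Optional list of `ligand_pose`.
#' @param path Optional JSON output path.
#' @return The manifest list, invisibly if written.
#' @export
structure_manifest <- function(protein, poses = NULL, path = NULL) {
  man <- list(
    n_atoms = nrow(protein$atoms),
    chains = as.list(table(protein$atoms$chain)),
    n_metals = sum(protein$atoms$is_metal),
    net_charge = if (all(is.na(protein$atoms$charge))) NULL
                 else sum(protein$atoms$charge))
  if (!is.null(poses))
    man$poses <- lapply(poses, function(p)
      list(name = p$name, n_atoms = nrow(p$atoms), n_bonds = nrow(p$bonds)))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(man))
  }
  man
}
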