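# Partial charges: iterative partial equalization of orbital
# electronegativities (PEOE / Gasteiger-Marsili) for ligands, and a
# table-driven per-atom charge model for proteins.

#' PEOE parameters
#'
#' Electronegativity polynomial coefficients chi(q) = a + b q + c q^2 per
#' element and hybridization state (the classical published values), the
#' hydrogen cation electronegativity, damping factor, and iteration count.
#'
#' @param damping Per-iteration damping base; charge transferred in iteration
#'   k is scaled by `damping^k`.
#' @param iterations Number of equalization iterations. Transfers shrink
#'   geometrically, so 12 iterations converge charges to ~1e-4 e.
#' @return Object of class `peoe_params`.
#' @export
peoe_params <- function(damping = 0.5, iterations = 12) {
  if (damping <= 0 || damping >= 1) stop("damping must be in (0,1)")
  if (iterations < 1) stop("iterations must be >= 1")
  coef <- list(
    "H"     = c(7.17,  6.24, -0.56),
    "C.sp3" = c(7.98,  9.18,  1.88),
    "C.sp2" = c(8.79,  9.32,  1.51),
    "C.sp"  = c(10.39, 9.45,  0.73),
    "N.sp3" = c(11.54, 10.82, 1.36),
    "N.sp2" = c(12.87, 11.15, 0.85),
    "N.sp"  = c(15.68, 11.70, -0.27),
    "O.sp3" = c(14.18, 12.92, 1.39),
    "O.sp2" = c(17.07, 13.79, 0.47),
    "F.sp3" = c(14.66, 13.85, 2.31),
    "Cl.sp3" = c(11.00, 9.69, 1.35),
    "Br.sp3" = c(10.08, 8.47, 1.16),
    "I.sp3"  = c(9.90,  7.96, 0.96),
    "S.sp3"  = c(10.14, 9.13, 1.38),
    "P.sp3"  = c(8.90,  8.24, 0.96))
  structure(list(coef = coef, h_cation = 20.02, damping = damping,
                 iterations = iterations), class = "peoe_params")
}

# Hybridization from bond orders and degree: any triple bond or two doubles
# -> sp; any double or aromatic (order 1.5) bond -> sp2; else sp3.
.hybridization <- function(el, bonds, n_atoms) {
  hyb <- rep("sp3", n_atoms)
  if (nrow(bonds) == 0) return(hyb)
  for (a in seq_len(n_atoms)) {
    ords <- c(bonds$order[bonds$i == a], bonds$order[bonds$j == a])
    if (any(ords >= 3) || sum(ords >= 2) >= 2) hyb[a] <- "sp"
    else if (any(ords >= 1.5)) hyb[a] <- "sp2"
  }
  hyb
}

#' Gasteiger (PEOE) partial charges for a ligand
#'
#' Iterative partial equalization of orbital electronegativities seeded from
#' formal charges: in iteration k, each bond transfers charge
#' `damping^k * (chi_hi - chi_lo) / chi_plus(lo)` from the less to the more
#' electronegative atom, where `chi_plus` is the cation electronegativity of
#' the less electronegative partner (20.02 for hydrogen). Deterministic;
#' conserves total charge exactly.
#'
#' @param ligand A `ligand_pose` with bond graph present.
#' @param params A [peoe_params()] object.
#' @param formal_charges Optional per-atom formal charges used to seed the
#'   iteration; defaults to all zero with any net `ligand$formal_charge`
#'   unassigned to a specific atom being rejected.
#' @return The pose with `atoms$charge` populated.
#' @export
gasteiger_charges <- function(ligand, params = peoe_params(),
                              formal_charges = NULL) {
  n <- nrow(ligand$atoms)
  el <- ligand$atoms$element
  bonds <- ligand$bonds
  hyb <- .hybridization(el, bonds, n)
  key <- ifelse(el == "H", "H", paste(el, hyb, sep = "."))
  # halogens/S/P are tabulated as sp3 regardless of inferred state
  key <- ifelse(el %in% c("F", "Cl", "Br", "I", "S", "P"),
                paste0(el, ".sp3"), key)
  unknown <- setdiff(unique(key), names(params$coef))
  if (length(unknown))
    stop("no PEOE parameters for atom type(s): ",
         paste(unknown, collapse = ", "))
  A <- do.call(rbind, params$coef[key])
  chi_plus <- ifelse(el == "H", params$h_cation, rowSums(A))
  if (is.null(formal_charges)) {
    formal_charges <- numeric(n)
    if (!is.null(ligand$formal_charge) && ligand$formal_charge != 0)
      stop("pose ", ligand$name, " has net formal charge ",
           ligand$formal_charge,
           "; supply per-atom formal_charges to seed the iteration")
  }
  if (length(formal_charges) != n) stop("formal_charges length mismatch")
  q <- as.numeric(formal_charges)
  damp <- 1
  transfer_hist <- numeric(params$iterations)
  for (k in seq_len(params$iterations)) {
    damp <- damp * params$damping
    chi <- A[, 1] + A[, 2] * q + A[, 3] * q^2
    dq <- numeric(n)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      d <- damp * abs(chi[j] - chi[i]) / chi_plus[lo]
      if (chi[j] > chi[i]) { dq[i] <- dq[i] + d; dq[j] <- dq[j] - d }
      else                 { dq[i] <- dq[i] - d; dq[j] <- dq[j] + d }
    }
    transfer_hist[k] <- if (length(dq)) max(abs(dq)) else 0
    q <- q + dq
  }
  if (abs(sum(q) - sum(formal_charges)) > 1e-6)
    stop("PEOE charge conservation violated")  # cannot happen; guards edits
  ligand$atoms$charge <- q
  attr(ligand, "peoe_transfer_history") <- transfer_hist
  ligand
}

#' Load a protein per-atom charge table
#'
#' TSV with columns `residue`, `atom`, `charge`. Residue `ALL` matches any
#' residue and is used for backbone atoms; specific residue rows take
#' precedence. The packaged default is a minimal amber-style table; users
#' supply a fuller table for real targets.
#'
#' @param path TSV path; default the packaged minimal table.
#' @return data.frame of class `charge_table`.
#' @export
load_charge_table <- function(path = .extdata("protein_charges.tsv")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "atom", "charge") %in% names(tab)))
    stop("charge table needs columns residue, atom, charge")
  class(tab) <- c("charge_table", class(tab))
  tab
}

#' Assign protein partial charges from a table
#'
#' Looks up every protein atom by (residue, atom name), falling back to the
#' `ALL`-residue backbone rows. Metal atoms take integer formal charges from
#' `metal_charges` (by residue name). Any unresolvable atom is an explicit
#' error naming residue and atom. The net protein charge is reported via
#' `message()`.
#'
#' @param protein A `protein_structure`.
#' @param charge_table A [load_charge_table()] data frame.
#' @param metal_charges Named numeric, e.g. `c(ZN = 2)`.
#' @return The protein with `atoms$charge` populated.
#' @export
protein_charge_assignment <- function(protein,
                                      charge_table = load_charge_table(),
                                      metal_charges = c(ZN = 2, MG = 2,
                                                        CA = 2, MN = 2,
                                                        FE = 2, NA. = 1,
                                                        K = 1)) {
  at <- protein$atoms
  names(metal_charges) <- sub("\\.$", "", names(metal_charges))
  spec_key <- paste(charge_table$residue, charge_table$atom)
  q <- rep(NA_real_, nrow(at))
  for (i in seq_len(nrow(at))) {
    if (at$is_metal[i]) {
      m <- metal_charges[at$resid[i]]
      if (is.na(m)) stop("no metal charge configured for residue ",
                         at$resid[i])
      q[i] <- m
      next
    }
    hit <- match(paste(at$resid[i], at$atom_name[i]), spec_key)
    if (is.na(hit)) hit <- match(paste("ALL", at$atom_name[i]), spec_key)
    if (is.na(hit))
      stop("no charge table entry for residue ", at$resid[i], " atom ",
           at$atom_name[i])
    q[i] <- charge_table$charge[hit]
  }
  protein$atoms$charge <- q
  message(sprintf("net protein charge: %+.4f e over %d atoms",
                  sum(q), length(q)))
  protein
}
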