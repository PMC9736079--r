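# Replacement energies, unit-range normalization, and the weighted Z-score
# ranking.

#' Energy components of one pose
#'
#' @param e_electrostatic kcal/mol (site-interaction energy).
#' @param e_hydrophobic kJ/mol.
#' @param e_vdw kJ/mol.
#' @param grid_id Provenance tag of the potential grid used.
#' @return `energy_components` list.
#' @export
energy_components <- function(e_electrostatic, e_hydrophobic, e_vdw,
                              grid_id = NA_character_) {
  v <- c(e_electrostatic, e_hydrophobic, e_vdw)
  if (any(!is.finite(v))) stop("non-finite energy component")
  structure(list(e_electrostatic = e_electrostatic,
                 e_hydrophobic = e_hydrophobic, e_vdw = e_vdw,
                 grid_id = grid_id), class = "energy_components")
}

#' Replacement energies of a query versus the cognate
#'
#' Channel-wise `E_query - E_cognate`: the energy cost of replacing the
#' cognate ligand by the query in the same pocket and the same ligand-free
#' potential. Negative values are favourable. Components computed against
#' different potential grids cannot be compared and raise an error.
#'
#' @param query,cognate `energy_components`.
#' @return `replacement_energies` list with `d_electrostatic` (kcal/mol),
#'   `d_hydrophobic`, `d_vdw` (kJ/mol).
#' @export
replacement_energy <- function(query, cognate) {
  if (!identical(query$grid_id, cognate$grid_id))
    stop("mixed provenance: query grid '", query$grid_id,
         "' vs cognate grid '", cognate$grid_id, "'")
  structure(list(
    d_electrostatic = query$e_electrostatic - cognate$e_electrostatic,
    d_hydrophobic = query$e_hydrophobic - cognate$e_hydrophobic,
    d_vdw = query$e_vdw - cognate$e_vdw,
    grid_id = query$grid_id), class = "replacement_energies")
}

#' Normalize a raw term onto the unit range
#'
#' Replacement energies: a favourable cost (`x <= 0`) maps to exactly 1; an
#' unfavourable cost decays as `1 - tanh(alpha x)`, continuous at zero.
#' Shape Euclidean distances (`favorable_low = TRUE`) must be non-negative
#' and map as `1 - tanh(alpha d)` so identical shapes score 1.
#'
#' @param x Raw value (replacement energy, or shape distance).
#' @param alpha Positive steepness coefficient absorbing the term's units.
#' @param favorable_low If `TRUE`, `x` is a distance and negative input is
#'   an error.
#' @return Value in [0, 1].
#' @export
normalize_term <- function(x, alpha, favorable_low = FALSE) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (favorable_low) {
    if (any(x < 0)) stop("shape distance cannot be negative")
    return(1 - tanh(alpha * x))
  }
  ifelse(x <= 0, 1, 1 - tanh(alpha * x))
}

#' Weighted Z-score of one ligand
#'
#' Weighted sum of the 14 normalized terms: the three replacement-energy
#' channels, pocket- and reference-shape similarities, the eight descriptor
#' similarities, and the atom-pair similarity. All terms must lie in [0,1];
#' with all terms at 1 and default weights the maximum is 19.
#'
#' @param terms Named list/vector with elements `elec`, `hyd`, `vdw`,
#'   `pocket_shape`, `ref_shape`, `desc` (length 8), `ap`.
#' @param w An [es_weights()] object.
#' @return The scalar Z.
#' @export
z_score <- function(terms, w = es_weights()) {
  need <- c("elec", "hyd", "vdw", "pocket_shape", "ref_shape", "desc", "ap")
  missing <- setdiff(need, names(terms))
  if (length(missing)) stop("missing term(s): ",
                            paste(missing, collapse = ", "))
  if (length(terms$desc) != 8) stop("desc must hold 8 similarities")
  vals <- c(terms$elec, terms$hyd, terms$vdw, terms$pocket_shape,
            terms$ref_shape, terms$desc, terms$ap)
  if (any(vals < -1e-9 | vals > 1 + 1e-9))
    stop("normalized terms must lie in [0,1]")
  w$w_elec * terms$elec + w$w_hyd * terms$hyd + w$w_vdw * terms$vdw +
    w$w_pocket * terms$pocket_shape + w$w_ref * terms$ref_shape +
    sum(w$w_desc * terms$desc) + w$w_ap * terms$ap
}

#' Rank scored ligands
#'
#' Orders records by descending Z; ties broken by the higher normalized
#' electrostatic term, then input order (logged via message). Duplicate
#' ligand names are an error.
#'
#' @param records data.frame with at least `name`, `Z`, and `n_elec` (the
#'   normalized electrostatic term) columns.
#' @return The data.frame reordered, with a `rank` column added.
#' @export
rank_ligands <- function(records) {
  if (anyDuplicated(records$name))
    stop("duplicate ligand names: ",
         paste(unique(records$name[duplicated(records$name)]),
               collapse = ", "))
  o <- order(-records$Z, -records$n_elec, seq_len(nrow(records)))
  if (anyDuplicated(records$Z))
    message("ties in Z broken by electrostatic term, then input order")
  out <- records[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
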